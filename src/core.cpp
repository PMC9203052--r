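#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// Target sequences are in-silico fully bisulfite-converted with IUPAC Y at
// CpG cytosines, so a read matches a target irrespective of its methylation
// pattern (Y pairs with C and T).
static inline bool base_match(char r, char t) {
  if (t == 'Y') return r == 'C' || r == 'T';
  return r == t;
}

static const int BIG = 1 << 28;

// Y-aware Hamming distance over the common prefix plus the length difference;
// an upper bound on the edit distance when lengths are equal.
static int hamming_like(const std::string& a, const std::string& b) {
  size_t n = std::min(a.size(), b.size());
  int d = (int)(std::max(a.size(), b.size()) - n);
  for (size_t i = 0; i < n; ++i)
    if (!base_match(a[i], b[i])) ++d;
  return d;
}

// Levenshtein distance restricted to a band of half-width k around the
// diagonal. Returns the exact distance when it is <= k, otherwise k + 1.
static int banded_dist(const std::string& a, const std::string& b, int k) {
  int na = (int)a.size(), nb = (int)b.size();
  if (std::abs(na - nb) > k) return k + 1;
  std::vector<int> prev(nb + 1, BIG), cur(nb + 1, BIG);
  for (int j = 0; j <= std::min(nb, k); ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    int lo = std::max(1, i - k), hi = std::min(nb, i + k);
    std::fill(cur.begin(), cur.end(), BIG);
    int rowmin = BIG;
    if (i <= k) { cur[0] = i; rowmin = i; }
    for (int j = lo; j <= hi; ++j) {
      int best = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
      if (cur[j - 1] + 1 < best) best = cur[j - 1] + 1;
      if (prev[j] + 1 < best) best = prev[j] + 1;
      cur[j] = best;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  return prev[nb] > k ? k + 1 : prev[nb];
}

// Exact distance if <= limit, else limit + 1 (band doubling).
static int edit_dist_limit(const std::string& a, const std::string& b,
                           int limit) {
  int maxd = (int)std::max(a.size(), b.size());
  if (limit > maxd) limit = maxd;
  if (limit < 0) limit = 0;
  int k = std::max(1, (int)std::abs((long)a.size() - (long)b.size()));
  if (k > limit) k = limit;
  while (true) {
    int d = banded_dist(a, b, k);
    if (d <= k) return d;
    if (k >= limit) return limit + 1;
    k = std::min(2 * k, limit);
  }
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  return edit_dist_limit(a, b, (int)std::max(a.size(), b.size()));
}

// Assign each read to the closest target by Y-aware edit distance.
// Ties (equal minimal distance against several targets) are broken by
// panel order and flagged. Reads shorter than half of every target are
// marked too_short (unassignable).
// [[Rcpp::export]]
List cpp_match_reads(CharacterVector reads, CharacterVector targets) {
  int nt = targets.size(), n = reads.size();
  std::vector<std::string> tg(nt);
  for (int t = 0; t < nt; ++t) tg[t] = as<std::string>(targets[t]);
  IntegerVector best_idx(n, NA_INTEGER), best_dist(n, NA_INTEGER);
  NumericVector sim(n, NA_REAL);
  LogicalVector tie(n, false), too_short(n, false);
  std::vector<int> ord(nt), qh(nt);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    bool all_short = true;
    for (int t = 0; t < nt; ++t)
      if (2 * rd.size() >= tg[t].size()) { all_short = false; break; }
    if (all_short || nt == 0) { too_short[i] = true; continue; }
    for (int t = 0; t < nt; ++t) { ord[t] = t; qh[t] = hamming_like(rd, tg[t]); }
    std::sort(ord.begin(), ord.end(),
              [&](int x, int y) { return qh[x] < qh[y]; });
    int bd = BIG, bt = -1;
    bool btie = false;
    for (int s = 0; s < nt; ++s) {
      int t = ord[s];
      int limit = (bd == BIG) ? (int)std::max(rd.size(), tg[t].size()) : bd;
      int d = edit_dist_limit(rd, tg[t], limit);
      if (d < bd) {
        bd = d; bt = t; btie = false;
      } else if (d == bd && bd <= limit) {
        btie = true;
        if (t < bt) bt = t;
      }
    }
    best_idx[i] = bt + 1;
    best_dist[i] = bd;
    sim[i] = 1.0 - (double)bd / (double)tg[bt].size();
    tie[i] = btie;
  }
  return List::create(_["marker"] = best_idx, _["distance"] = best_dist,
                      _["similarity"] = sim, _["tie"] = tie,
                      _["too_short"] = too_short);
}

// Global alignment traceback mapping target positions (1-based) to read
// positions; 0 where the target base aligns to a gap.
static void nw_map(const std::string& r, const std::string& t,
                   std::vector<int>& map) {
  int nr = (int)r.size(), nt = (int)t.size();
  std::vector<int> dp((nr + 1) * (nt + 1));
  auto at = [&](int i, int j) -> int& { return dp[i * (nt + 1) + j]; };
  for (int i = 0; i <= nr; ++i) at(i, 0) = i;
  for (int j = 0; j <= nt; ++j) at(0, j) = j;
  for (int i = 1; i <= nr; ++i)
    for (int j = 1; j <= nt; ++j) {
      int best = at(i - 1, j - 1) + (base_match(r[i - 1], t[j - 1]) ? 0 : 1);
      best = std::min(best, at(i - 1, j) + 1);
      best = std::min(best, at(i, j - 1) + 1);
      at(i, j) = best;
    }
  map.assign(nt + 1, 0);
  int i = nr, j = nt;
  while (i > 0 && j > 0) {
    int d = at(i - 1, j - 1) + (base_match(r[i - 1], t[j - 1]) ? 0 : 1);
    if (at(i, j) == d) { map[j] = i; --i; --j; }
    else if (at(i, j) == at(i - 1, j) + 1) { --i; }
    else { map[j] = 0; --j; }
  }
  while (j > 0) { map[j] = 0; --j; }
}

// Read the dinucleotide at each expected CpG position of the assigned
// target: CG -> 'C' (methylated), TG -> 'T' (unmethylated), anything else
// '?' (ambiguous); a CpG aligned to a gap or beyond the read end -> '.'
// (missing). Same-length reads whose edit distance equals their Y-aware
// Hamming distance are mapped positionally (an optimal all-substitution
// alignment); everything else goes through full global alignment.
// [[Rcpp::export]]
List cpp_call_patterns(CharacterVector reads, IntegerVector marker,
                       IntegerVector distance, CharacterVector targets,
                       List cpg_pos) {
  int n = reads.size(), nt = targets.size();
  std::vector<std::string> tg(nt);
  std::vector<std::vector<int>> ps(nt);
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    IntegerVector p = cpg_pos[t];
    ps[t] = std::vector<int>(p.begin(), p.end());
  }
  CharacterVector pattern(n, NA_STRING);
  IntegerVector n_missing(n, NA_INTEGER), n_ambiguous(n, NA_INTEGER);
  std::vector<int> map;
  for (int i = 0; i < n; ++i) {
    if (marker[i] == NA_INTEGER) continue;
    int t = marker[i] - 1;
    std::string rd = as<std::string>(reads[i]);
    int nr = (int)rd.size(), ntg = (int)tg[t].size();
    bool identity = (nr == ntg) &&
      (distance[i] != NA_INTEGER && hamming_like(rd, tg[t]) == distance[i]);
    if (!identity) nw_map(rd, tg[t], map);
    std::string pat(ps[t].size(), '.');
    int miss = 0, ambig = 0;
    for (size_t c = 0; c < ps[t].size(); ++c) {
      int p = ps[t][c];
      int i1, i2;
      if (identity) { i1 = p; i2 = p + 1; if (i2 > nr) i2 = 0; }
      else { i1 = map[p]; i2 = (p + 1 <= ntg) ? map[p + 1] : 0; }
      if (i1 <= 0 || i2 <= 0 || i1 > nr || i2 > nr) { ++miss; continue; }
      char c1 = rd[i1 - 1], c2 = rd[i2 - 1];
      if (c1 == 'C' && c2 == 'G') pat[c] = 'C';
      else if (c1 == 'T' && c2 == 'G') pat[c] = 'T';
      else { pat[c] = '?'; ++ambig; }
    }
    pattern[i] = pat;
    n_missing[i] = miss;
    n_ambiguous[i] = ambig;
  }
  return List::create(_["pattern"] = pattern, _["n_missing"] = n_missing,
                      _["n_ambiguous"] = n_ambiguous);
}

// In-silico bisulfite chemistry for one amplicon template: every
// unmethylated C deaminates to T with probability conversion_rate; a
// methylated CpG C deaminates (inappropriately) with probability
// inappropriate_rate. A/G/T are untouched; length is preserved.
// Patterns are strings over {M,U}, one char per CpG of the template.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector cpp_convert_molecules(std::string tmpl, IntegerVector cpg_pos,
                                      CharacterVector patterns,
                                      double conversion_rate,
                                      double inappropriate_rate) {
  int L = (int)tmpl.size(), n = patterns.size();
  // c_sites: position (0-based) of every C; cpg_index: index into the
  // pattern for CpG cytosines, -1 for non-CpG cytosines.
  std::vector<int> c_sites, cpg_index;
  std::vector<int> is_cpg(L, -1);
  for (int k = 0; k < cpg_pos.size(); ++k) is_cpg[cpg_pos[k] - 1] = k;
  for (int p = 0; p < L; ++p)
    if (tmpl[p] == 'C') { c_sites.push_back(p); cpg_index.push_back(is_cpg[p]); }
  CharacterVector out(n);
  std::string buf;
  for (int m = 0; m < n; ++m) {
    buf = tmpl;
    const char* pat = CHAR(STRING_ELT(patterns, m));
    for (size_t s = 0; s < c_sites.size(); ++s) {
      int ci = cpg_index[s];
      double p_conv = (ci < 0) ? conversion_rate
                    : (pat[ci] == 'U' ? conversion_rate : inappropriate_rate);
      if (p_conv > 0 && unif_rand() < p_conv) buf[c_sites[s]] = 'T';
    }
    out[m] = buf;
  }
  return out;
}

// Per-base substitution sequencing errors at a uniform rate; the number of
// errors per read is binomial and positions are uniform.
// [[Rcpp::export]]
CharacterVector cpp_add_seq_errors(CharacterVector seqs, double error_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int k = (int)R::rbinom((double)L, error_rate);
    for (int e = 0; e < k; ++e) {
      int pos = (int)(unif_rand() * L);
      if (pos >= L) pos = L - 1;
      char cur = s[pos], nb;
      do { nb = bases[(int)(unif_rand() * 4) % 4]; } while (nb == cur);
      s[pos] = nb;
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
  int n = quals.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    int L = (int)std::strlen(q);
    if (L == 0) { out[i] = NA_REAL; continue; }
    long s = 0;
    for (int j = 0; j < L; ++j) s += q[j] - 33;
    out[i] = (double)s / L;
  }
  return out;
}
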