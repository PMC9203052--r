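# Independent oracles used across the suite. These deliberately use the
# dumbest correct algorithm (enumeration, all-pairs loops) so they share no
# code with the implementation they check.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combs <- utils::combn(length(pooled), n1)
  us <- apply(combs, 2L, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Tie-halved concordance AUC by looping over all (positive, negative) pairs.
auc_pairs <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Per-locus exhaustive check of the marker selection rule.
select_brute <- function(m, labels, target, t_low, t_high) {
  hits <- character(0)
  for (i in seq_len(nrow(m))) {
    tv <- m[i, labels %in% target]
    bv <- m[i, !labels %in% target]
    if (anyNA(tv) || anyNA(bv)) next
    if (max(tv) <= t_low && min(bv) >= t_high) hits <- c(hits, rownames(m)[i])
  }
  hits
}

# Deterministic bisulfite conversion (rate 1 / 0) done with plain string
# surgery, for checking the stochastic converter at its corners.
convert_det <- function(sequence, cpg_pos, pattern) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  states <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (p in which(ch == "C")) {
    k <- match(p, cpg_pos)
    if (is.na(k) || states[k] == "U") ch[p] <- "T"
  }
  paste(ch, collapse = "")
}

# Small fixed panel for hand-checked read tests.
tiny_panel <- function() {
  generate_marker_panel(
    n_per_cell_type = c(neuron = 1, astrocyte = 1, oligodendrocyte = 1,
                        whole_brain = 1),
    n_cpgs_range = c(3L, 4L), amplicon_length = 60L, seed = 99L)
}

# Molecule-call tibble built directly from simulated molecules (skipping
# sequencing), for quantification tests.
calls_from_molecules <- function(mol, sample_id = "s1") {
  tibble::tibble(
    read_id = mol$molecule_id,
    sample_id = sample_id,
    marker_id = mol$marker_id,
    similarity = 1,
    pattern = chartr("MU", "CT", mol$pattern),
    status = "pass")
}
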