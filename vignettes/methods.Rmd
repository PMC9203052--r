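---
title: "Methods: quantifying brain-derived cfDNA from bisulfite amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying brain-derived cfDNA from bisulfite amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the model behind `cfbrain`, the parameters that
matter, the design decisions taken where the method left room, and what the
simulation-based tests do and do not establish about real plasma data.

# The measurement model

A plasma sample contains cfDNA from many tissues. At a marker locus chosen
to be unmethylated only in one brain cell class, a molecule of brain origin
carries unmethylated CpGs, while molecules from other tissues carry
methylated ones. After bisulfite conversion, unmethylated cytosines read as
T and methylated cytosines as C, so the originating class of each sequenced
molecule is legible from its CpG dinucleotides: `TG` at every expected CpG
marks a brain-derived molecule.

The per-marker estimate is a simple binomial proportion: among molecules
that pass processing, the fraction whose every CpG reads unmethylated.
Requiring *all* CpGs keeps the false-positive rate per molecule at roughly
$(i + e/3)^k$ for inappropriate-conversion rate $i$, sequencing error rate
$e$ and $k$ CpGs — of order $10^{-6}$ at the defaults — which is what makes
single-molecule counting workable at fractions of $10^{-3}$ and below.

Absolute quantification multiplies this fraction by the sample's total
cfDNA concentration, measured **before** bisulfite treatment (which destroys
a large, variable share of the input — commonly 60–90% of molecules):

$$\mathrm{GE/mL} = \hat f \times \frac{c \,[\mathrm{ng/mL}] \times 1000}{3.3\,[\mathrm{pg/genome}]}$$

Because the fraction is unbiased under uniform molecule loss (the thinning
tests verify this), bisulfite degradation costs sensitivity but not
accuracy. The genome-mass constant 3.3 pg/haploid genome is declared and
config-exposed (`pg_per_haploid_genome`); every rank-based cohort statistic
(Mann-Whitney, Spearman, AUC, sensitivity at fixed specificity) is invariant
to it.

Cell-type signals are unweighted means of the marker GE/mL values within
each class; the combined brain score is the sum of the neuron, astrocyte and
oligodendrocyte means. Whole-brain markers — loci unmethylated in all brain
cell types — are reported separately and excluded from the sum by default
(`include_whole_brain = TRUE` overrides), since their signal largely
duplicates the cell-type markers'. A parallel fraction-based score without
the concentration multiplication is always emitted; the concentration-based
score is the default for ROC analysis, and both are available because either
aggregation is defensible.

# Read processing: choices and their reasons

**Similarity metric.** Reads are assigned to the amplicon maximizing
$1 - d/L$, where $d$ is the Levenshtein distance to the in-silico fully
converted target and $L$ the target length, with an acceptance threshold of
0.8. Edit distance (rather than Hamming) tolerates the occasional indel from
sequencing. CpG cytosines in the target are the ambiguity code `Y`,
matching C and T equally, so a molecule's methylation state cannot influence
its assignment — methylated and unmethylated molecules of one marker score
identically, which the tests assert. Ties between targets are broken by
panel order and flagged. Reads shorter than half of every target are
unassignable. The matcher is exact: a banded dynamic program with iterative
band doubling, plus branch-and-bound across the panel ordered by a fast
Hamming screen, returns the true minimum distance at full-cohort throughput.

**Quality filter.** Mean Phred ≥ 30, boundary passing. The threshold is a
config default, not a derived value; Illumina amplicon runs comfortably
exceed it.

**CpG calling.** Expected CpG positions are mapped through the read-target
alignment (positionally when the optimal alignment is substitution-only,
via full global alignment otherwise). `CG` calls methylated, `TG`
unmethylated; any other dinucleotide is ambiguous and — under the default
strict policy — invalidates the whole molecule (`fail_ambiguous_cpg`).
Strictness protects the fully-unmethylated count from miscalls at single
sites; a lenient policy (ambiguous states retained, molecule kept) exists
for sensitivity analyses. A read not covering every expected CpG fails as
`fail_missing_cpg`, per the rule that a molecule must contain all expected
CpGs. Every read ends in exactly one status; the per-status counts in the
run report always sum to the input.

**Orientation.** Amplicon sequencing is directional: reads are treated as
top-strand, no reverse-complement search. Barcodes are matched exactly by
default (TruSeq indices are mutually distant); one mismatch is allowed by
configuration.

# The synthetic-data generator

The generator emulates the study's inputs: mixtures of fully unmethylated
(brain) and fully methylated (background) molecules per marker at a
controlled fraction; bisulfite chemistry as independent per-cytosine
Bernoulli conversion (unmethylated C→T with probability `conversion_rate`,
default 0.99; methylated C→T with `inappropriate_rate`, default 0.005);
substitution-only sequencing errors (default $10^{-3}$ per base); constant
Q37 qualities; barcoded FASTQ with truth tables. Cohort simulation draws
per-sample, per-cell-type brain signals from a lognormal (controls:
`meanlog = log(2)`, `sdlog = 0.5` GE/mL per cell type, i.e. a combined
score around 6 GE/mL with ~50% biological CV) and total cfDNA around
7 ng/mL (controls) and 9 ng/mL (cases), with a multiplicative case shift of
the brain signal (default 2). Dose records for patients are olanzapine
equivalents, independent of the cfDNA signal unless an association is
requested.

Defaults that the method itself does not pin down were chosen once on
domain grounds: amplicons are 100 bp with 3–6 CpGs (plasma cfDNA fragments
of ~170 bp bound practical amplicon length); sequencing depth is 30,000
molecules per marker per sample (deep targeted sequencing; the real depth
per marker is not a published quantity).

Two cohort modes share one underlying model. `"reads"` mode writes
per-sample FASTQ through the full chemistry and is used for end-to-end
round trips. `"counts"` mode draws the per-marker count of fully
unmethylated molecules directly from the same binomial law, skipping
sequence emulation; it is what makes 500-replicate calibration studies
affordable, and a dedicated test confirms the two modes recover the same
underlying signal.

**What the generator does not model** — and what passing tests therefore do
not establish about real plasma: PCR amplification bias and duplicates,
chimeric molecules, indel sequencing errors (configurable but off by
default), strand-specific bisulfite artifacts, fragment-length effects,
copy-number variation of source tissue, and above all *biological
background*: real leukocyte DNA contains rare genuinely unmethylated
molecules at any locus, which in the wet assay — not conversion chemistry —
set the practical detection floor. In the simulation the background is
perfectly methylated by design, so the in-silico detection limit of the
dilution experiment (0.05% under the shipped conditions) is better than a
wet-lab assay should be expected to achieve; the simulation conditions
bound what the *pipeline* can resolve, not what plasma biology allows.

# Marker selection

Selection works on a beta-value matrix with labelled reference samples. The
rule is absolutist on purpose: the maximum beta over target samples must
not exceed `t_low` (default 0.2) and the minimum over every background
sample must reach `t_high` (default 0.8) — worst-case specificity rather
than group means, matching the requirement that a marker be unmethylated
specifically in its class and methylated in *all* others. The numeric
cutoffs are conventional array thresholds, config-exposed, because the
original comparative analysis did not publish its exact statistic.
Candidates are ranked by margin (background min − target max). Whole-brain
markers are selected with the union of brain labels as the target; loci
passing the union test are assigned to `whole_brain` and removed from the
per-cell-type lists (most-specific-class rule). Loci with missing betas in
any deciding group are excluded and reported, never imputed. Selection is
invariant to row and column order, monotone in both thresholds, and matches
an exhaustive per-locus oracle on every tested matrix.

# Cohort statistics: numerical conventions

* **Mann-Whitney**: exact null distribution when $n_1 n_2 \le 400$ with no
  ties, else normal approximation with tie and continuity correction. $U$
  counts pairs where the first group exceeds the second, ties half. The
  exact/asymptotic switch can shift small p-values in the third decimal,
  which is why published p-values from an unspecified variant can only be
  matched to that resolution.
* **AUC** is computed from midranks (tie-halved concordance), making
  $\mathrm{AUC} \equiv U/(n_1 n_0)$ an identity, checked exactly on random
  cohorts. Orientation is fixed — higher score ⇒ patient — and never
  auto-flipped, so an AUC below 0.5 is reported as such.
* **CI**: DeLong by default; stratified bootstrap (2000 resamples, seeded)
  as the alternative. The p-value against AUC = 0.5 is the Mann-Whitney p
  of the same scores.
* **Sensitivity at specificity** uses only attainable empirical thresholds
  with specificity ≥ the target, no interpolation — conservative, and the
  reported threshold actually achieves the reported operating point. With
  degenerate all-equal scores the answer is 0 at threshold +∞.
* **Dose screen**: 18 variables (13 markers, 4 cell-type averages, total
  cfDNA) × 2 dose windows × 4 tests; Benjamini-Hochberg across the whole
  grid (Bonferroni via `adjust_method`). Cells with fewer than 3 complete
  pairs or constant inputs are reported missing with a reason, never
  silently dropped. The categorical split defaults to the patient median
  dose.
* **Dose equivalence**: shipped consensus factors (olanzapine 20 mg/day
  reference) as editable TSV config data; unknown drugs abort with the
  offending names, never contribute silently as zero.
* Zero-coverage markers propagate as missing, not zero, and a cell type
  with no covered markers silences the combined score rather than deflating
  it.

# Problem sizes used in validation

The shipped validation suite runs at the study's own scale: dilution series
at fractions {0, 5·10⁻⁴, 10⁻³, 10⁻²} × 30,000 molecules × 13 markers × 10
seeds through the full read pipeline; 500-replicate null-cohort calibration
(rejection rate of the combined-score test confined to [0.02, 0.09] at
α = 0.05); 100-replicate recovery of a doubled case signal in 29 vs 31
samples; 100-seed thinning at 75% loss; and exact-identity checks of the
rank statistics against enumeration oracles for all group sizes ≤ 8.

# Known limitations

Beyond the generator's simplifications listed above: the pipeline is
single-end and top-strand only; no UMI deduplication (the assay counts
molecules through read counts, so PCR bias is a real-world caveat); marker
selection implements the qualitative specificity criterion, not the
original unpublished scoring; and cohort statistics are deliberately
rank-based and two-sided throughout, so parametric effect-size estimates
are out of scope.
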