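#' Fraction of fully unmethylated molecules per sample and marker
#'
#' Among passing molecule calls, counts molecules whose every CpG state is
#' unmethylated (all `T`); molecules with any methylated or uncalled CpG do
#' not count. Markers with zero passing molecules yield a missing fraction
#' (never zero) with a warning.
#'
#' @param calls Molecule-call tibble from [process_reads()].
#' @param panel Marker panel tibble; markers absent from `calls` are
#'   completed with zero counts and missing fractions.
#' @return Tibble with `sample_id`, `marker_id`, `n_pass`,
#'   `n_fully_unmethylated`, `fraction`.
#' @export
fraction_fully_unmethylated <- function(calls, panel) {
  pass <- calls[calls$status == "pass", , drop = FALSE]
  fully <- !is.na(pass$pattern) & grepl("^T+$", pass$pattern)
  counts <- tibble(sample_id = pass$sample_id, marker_id = pass$marker_id,
                   fully = fully) |>
    group_by(.data$sample_id, .data$marker_id) |>
    summarise(n_pass = dplyr::n(),
              n_fully_unmethylated = sum(.data$fully), .groups = "drop")
  samples <- unique(calls$sample_id)
  grid <- tidyr::expand_grid(sample_id = samples, marker_id = panel$marker_id)
  out <- grid |>
    left_join(counts, by = c("sample_id", "marker_id")) |>
    mutate(n_pass = tidyr::replace_na(.data$n_pass, 0L),
           n_fully_unmethylated = tidyr::replace_na(.data$n_fully_unmethylated, 0L),
           fraction = ifelse(.data$n_pass > 0,
                             .data$n_fully_unmethylated / .data$n_pass,
                             NA_real_))
  if (anyNA(out$fraction)) {
    warn(sprintf("%d sample x marker combinations have zero passing molecules; fraction set to missing",
                 sum(is.na(out$fraction))))
  }
  out
}

#' Convert an unmethylated fraction to genome equivalents per mL
#'
#' Multiplies the fraction of fully unmethylated molecules by the total
#' cfDNA concentration of the sample, expressed as haploid genomes per mL:
#' `fraction * total_cfdna_ng_per_ml * 1000 / pg_per_haploid_genome`. The
#' concentration is the one measured before bisulfite conversion, which makes
#' the readout robust to bisulfite-induced DNA degradation.
#'
#' @param fraction Unmethylated-molecule fraction(s) in \[0, 1\].
#' @param total_cfdna_ng_per_ml Total cfDNA concentration (ng per mL plasma).
#' @param pg_per_haploid_genome Mass of a haploid genome in pg (default 3.3).
#' @return Genome equivalents per mL, same length as `fraction`.
#' @export
genome_equivalents_per_ml <- function(fraction, total_cfdna_ng_per_ml,
                                      pg_per_haploid_genome = 3.3) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE) ||
      any(total_cfdna_ng_per_ml < 0, na.rm = TRUE) ||
      pg_per_haploid_genome <= 0) {
    abort("fractions must be in [0, 1] and concentrations non-negative",
          class = "cfbrain_input_error")
  }
  fraction * total_cfdna_ng_per_ml * 1000 / pg_per_haploid_genome
}

#' Per-marker quantification table
#'
#' Combines [fraction_fully_unmethylated()] with sample metadata to produce
#' the per-marker readouts: counts, fractions and genome equivalents per mL.
#'
#' @param calls Molecule-call tibble from [process_reads()].
#' @param metadata Tibble with `sample_id` and `total_cfdna_ng_per_ml`.
#' @param panel Marker panel tibble.
#' @param pg_per_haploid_genome Genome mass constant (pg).
#' @return Tibble with one row per sample x marker: `sample_id`,
#'   `marker_id`, `cell_type`, `n_pass`, `n_fully_unmethylated`, `fraction`,
#'   `ge_per_ml`.
#' @export
quantify_markers <- function(calls, metadata, panel,
                             pg_per_haploid_genome = 3.3) {
  if (!all(c("sample_id", "total_cfdna_ng_per_ml") %in% names(metadata))) {
    abort("metadata needs sample_id and total_cfdna_ng_per_ml columns",
          class = "cfbrain_input_error")
  }
  fraction_fully_unmethylated(calls, panel) |>
    left_join(select(panel, "marker_id", "cell_type"), by = "marker_id") |>
    left_join(select(metadata, "sample_id", "total_cfdna_ng_per_ml"),
              by = "sample_id") |>
    mutate(ge_per_ml = genome_equivalents_per_ml(
      .data$fraction, .data$total_cfdna_ng_per_ml, pg_per_haploid_genome)) |>
    select("sample_id", "marker_id", "cell_type", "n_pass",
           "n_fully_unmethylated", "fraction", "ge_per_ml",
           "total_cfdna_ng_per_ml")
}

#' Aggregate marker quantities into cell-type signals
#'
#' Unweighted mean of `ge_per_ml` (and of `fraction`) over the markers of
#' each cell type; markers with missing values are excluded from the mean
#' and the number used is reported. A cell type whose markers are all
#' missing yields a missing signal.
#'
#' @param marker_quant Tibble from [quantify_markers()].
#' @return Tibble with `sample_id`, `cell_type`, `mean_ge_per_ml`,
#'   `mean_fraction`, `n_markers_used`.
#' @export
aggregate_cell_types <- function(marker_quant) {
  marker_quant |>
    group_by(.data$sample_id, .data$cell_type) |>
    summarise(
      n_markers_used = sum(!is.na(.data$ge_per_ml)),
      mean_ge_per_ml = if (any(!is.na(.data$ge_per_ml)))
        mean(.data$ge_per_ml, na.rm = TRUE) else NA_real_,
      mean_fraction = if (any(!is.na(.data$fraction)))
        mean(.data$fraction, na.rm = TRUE) else NA_real_,
      .groups = "drop")
}

#' Per-sample summary: cell-type signals and combined brain score
#'
#' The combined brain score is the sum of the neuron, astrocyte and
#' oligodendrocyte mean signals; whole-brain markers are reported separately
#' and excluded from the sum unless `include_whole_brain = TRUE`. A parallel
#' fraction-based score (no concentration multiplication) is also emitted.
#' If any contributing cell-type signal is missing the combined score is
#' missing.
#'
#' @param marker_quant Tibble from [quantify_markers()].
#' @param include_whole_brain Include the whole-brain signal in the sum.
#' @return Tibble with one row per sample: cell-type `ge_per_ml` means as
#'   columns, `combined_brain_score`, `combined_fraction_score`,
#'   `total_cfdna_ng_per_ml`.
#' @export
sample_summary <- function(marker_quant, include_whole_brain = FALSE) {
  ct <- aggregate_cell_types(marker_quant)
  sum_types <- c("neuron", "astrocyte", "oligodendrocyte",
                 if (include_whole_brain) "whole_brain")
  sum_types <- intersect(sum_types, unique(ct$cell_type))
  wide_ge <- tidyr::pivot_wider(ct[, c("sample_id", "cell_type", "mean_ge_per_ml")],
                                names_from = "cell_type",
                                values_from = "mean_ge_per_ml")
  combined <- ct |>
    filter(.data$cell_type %in% sum_types) |>
    group_by(.data$sample_id) |>
    summarise(
      combined_brain_score = if (anyNA(.data$mean_ge_per_ml)) NA_real_ else
        sum(.data$mean_ge_per_ml),
      combined_fraction_score = if (anyNA(.data$mean_fraction)) NA_real_ else
        sum(.data$mean_fraction),
      .groups = "drop")
  meta <- dplyr::distinct(marker_quant[, c("sample_id", "total_cfdna_ng_per_ml")])
  wide_ge |>
    left_join(combined, by = "sample_id") |>
    left_join(meta, by = "sample_id")
}

#' Randomly thin molecule calls
#'
#' Removes a uniform random subset of molecules, emulating the DNA loss of
#' bisulfite treatment (typically 60-90 percent of input molecules). Thinning
#' is unbiased for the unmethylated fraction because methylated and
#' unmethylated molecules are removed at the same rate.
#'
#' @param calls Molecule-call tibble.
#' @param keep_fraction Fraction of molecules retained.
#' @param seed Optional integer seed.
#' @return The thinned calls tibble.
#' @export
thin_calls <- function(calls, keep_fraction = 0.25, seed = NULL) {
  assert_rate(keep_fraction, "keep_fraction")
  with_seed_if(seed, {
    keep <- runif(nrow(calls)) < keep_fraction
    calls[keep, , drop = FALSE]
  })
}
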