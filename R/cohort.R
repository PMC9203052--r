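#' Assemble a cohort table from quantification output and metadata
#'
#' One row per sample: group label, cell-type signals, combined scores,
#' wide per-marker `ge_<marker_id>` columns, total cfDNA and any metadata
#' columns (demographics, dose equivalents).
#'
#' @param marker_quant Tibble from [quantify_markers()].
#' @param metadata Tibble with `sample_id` plus clinical columns (`group`,
#'   `age`, `sex`, dose variables, ...).
#' @param include_whole_brain Passed to [sample_summary()].
#' @return Cohort tibble.
#' @export
cohort_table <- function(marker_quant, metadata,
                         include_whole_brain = FALSE) {
  summ <- sample_summary(marker_quant, include_whole_brain)
  wide <- marker_quant |>
    mutate(name = paste0("ge_", .data$marker_id)) |>
    select("sample_id", "name", "ge_per_ml") |>
    tidyr::pivot_wider(names_from = "name", values_from = "ge_per_ml")
  meta_cols <- setdiff(names(metadata), c("total_cfdna_ng_per_ml", "barcode",
                                          "fastq"))
  metadata[meta_cols] |>
    left_join(summ, by = "sample_id") |>
    left_join(wide, by = "sample_id")
}

#' Read a cohort table from disk with flexible column mapping
#'
#' Reads TSV or CSV (by extension) and renames columns to the standard
#' layout through `mapping`, e.g.
#' `list(sample_id = "ID", group = "Status", ...)`. Group labels can be
#' recoded via `group_levels = c(control = "Healthy", patient = "FEP")`.
#' Missing values may be encoded as `"."`.
#'
#' @param path File path.
#' @param mapping Named list, standard name -> column name in the file.
#' @param group_levels Optional named character vector recoding the group
#'   column to `control`/`patient`.
#' @return Cohort tibble.
#' @export
read_cohort <- function(path, mapping = list(), group_levels = NULL) {
  reader <- if (grepl("\\.csv$", path)) readr::read_csv else readr::read_tsv
  x <- reader(path, na = c("", "NA", "."), show_col_types = FALSE,
              progress = FALSE)
  for (std in names(mapping)) {
    raw <- mapping[[std]]
    if (!raw %in% names(x)) {
      abort(paste("mapped column not found:", raw),
            class = "cfbrain_input_error")
    }
    names(x)[names(x) == raw] <- std
  }
  if (!is.null(group_levels) && "group" %in% names(x)) {
    rev_map <- setNames(names(group_levels), group_levels)
    x$group <- unname(rev_map[as.character(x$group)])
  }
  as_tibble(x)
}

#' Headline cohort statistics
#'
#' Reproduces the cohort-level summary of the assay: Mann-Whitney
#' patient-vs-control comparison for each signal, the ROC of the combined
#' brain score with AUC, 95 percent CI and p-value against chance,
#' sensitivity at fixed specificity, and per-cell-type AUCs.
#'
#' @param cohort Cohort tibble with a two-level `group` column
#'   (`control` / `patient`).
#' @param score Column used for the headline ROC (tidy-eval; default
#'   `combined_brain_score`; use `combined_fraction_score` for the
#'   fraction-based variant).
#' @param signals Columns compared between groups with Mann-Whitney.
#' @param target_specificity Specificity bound for the sensitivity readout.
#' @param positive Group level treated as positive.
#' @return Object of class `cfb_headline`: `group_tests` tibble, `roc`
#'   (`cfb_roc`), `sensitivity` tibble, `cell_type_aucs` tibble.
#' @export
cohort_headline_stats <- function(cohort, score = combined_brain_score,
                                  signals = c("total_cfdna_ng_per_ml",
                                              "neuron", "astrocyte",
                                              "oligodendrocyte",
                                              "whole_brain",
                                              "combined_brain_score"),
                                  target_specificity = 0.90,
                                  positive = "patient") {
  signals <- intersect(signals, names(cohort))
  group_tests <- purrr::map_dfr(signals, function(s) {
    mw <- mann_whitney.default(cohort[[s]][cohort$group == positive],
                               cohort[[s]][cohort$group != positive])
    tibble(signal = s, U = mw$U, p_value = mw$p_value)
  })
  roc <- roc_analysis.default(pull(cohort, {{ score }}), cohort$group,
                              positive = positive)
  sens <- sensitivity_at_specificity(roc, target_specificity)
  ct <- intersect(c("neuron", "astrocyte", "oligodendrocyte", "whole_brain"),
                  names(cohort))
  ct_aucs <- purrr::map_dfr(ct, function(s) {
    r <- roc_analysis.default(cohort[[s]], cohort$group, positive = positive)
    tibble(cell_type = s, auc = r$auc,
           ci_low = r$auc_ci_95[1], ci_high = r$auc_ci_95[2])
  })
  structure(list(group_tests = group_tests, roc = roc, sensitivity = sens,
                 cell_type_aucs = ct_aucs),
            class = "cfb_headline")
}

#' @export
print.cfb_headline <- function(x, ...) {
  cat("Group comparisons (Mann-Whitney):\n")
  print(as.data.frame(x$group_tests), row.names = FALSE)
  print(x$roc)
  cat(sprintf("Sensitivity at %.0f%% specificity: %.2f (threshold %.3g)\n",
              100 * x$sensitivity$target_specificity,
              x$sensitivity$sensitivity, x$sensitivity$threshold))
  invisible(x)
}
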