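#' Mann-Whitney U test
#'
#' Two-sample rank test with the exact null distribution when
#' `n_x * n_y <= 400` and there are no ties, and the normal approximation
#' with tie and continuity correction otherwise. `U` counts pairs in which
#' the first group exceeds the second (ties counted one half), so
#' `U / (n_x * n_y)` is the concordance probability.
#'
#' Methods exist for numeric vectors (`mann_whitney(x, y)`) and for data
#' frames (`mann_whitney(data, value, group)`, tidy-eval columns; the first
#' group level plays the role of `x`).
#'
#' @param x Numeric vector, or a data frame.
#' @param ... Passed between methods.
#' @return An object of class `cfb_mw` with elements `U`, `p_value`, `n_x`,
#'   `n_y`, `exact`, `alternative`. Has [tidy()] and [glance()] methods.
#' @export
mann_whitney <- function(x, ...) UseMethod("mann_whitney")

#' @rdname mann_whitney
#' @param y Numeric vector (second group).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @export
mann_whitney.default <- function(x, y, alternative = "two.sided", ...) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (!length(x) || !length(y)) {
    abort("both groups need at least one non-missing value",
          class = "cfbrain_input_error")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400L) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE))
  structure(list(U = unname(wt$statistic), p_value = unname(wt$p.value),
                 n_x = length(x), n_y = length(y), exact = exact,
                 alternative = alternative),
            class = "cfb_mw")
}

#' @rdname mann_whitney
#' @param value,group Columns of the data frame (tidy-eval) holding the
#'   measurement and the two-level group.
#' @export
mann_whitney.data.frame <- function(x, value, group,
                                    alternative = "two.sided", ...) {
  v <- pull(x, {{ value }})
  g <- pull(x, {{ group }})
  keep <- !is.na(g)
  v <- v[keep]; g <- as.character(g[keep])
  lv <- if (is.factor(pull(x, {{ group }}))) levels(pull(x, {{ group }})) else
    unique(g)
  if (length(lv) != 2L) {
    abort("`group` must have exactly two levels", class = "cfbrain_input_error")
  }
  out <- mann_whitney.default(v[g == lv[1]], v[g == lv[2]],
                              alternative = alternative)
  out$groups <- lv
  out
}

#' @export
print.cfb_mw <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d, %s), p = %.4g\n",
              x$U, x$n_x, x$n_y,
              if (x$exact) "exact" else "normal approximation", x$p_value))
  invisible(x)
}

#' Empirical ROC curve with AUC, confidence interval and null test
#'
#' Builds the empirical ROC for distinguishing the positive class (higher
#' scores = positive; the orientation is fixed, never auto-flipped). The AUC
#' is the tie-halved concordance probability, identical to the trapezoidal
#' area under the empirical curve and to the Mann-Whitney statistic
#' `U / (n1 * n0)`. The 95 percent CI uses DeLong's method by default or a
#' seeded stratified bootstrap; the p-value against AUC = 0.5 comes from the
#' Mann-Whitney test on the same scores.
#'
#' @param x Numeric scores, or a data frame.
#' @param ... Passed between methods.
#' @return Object of class `cfb_roc`: `points` (tibble `threshold`,
#'   `sensitivity`, `specificity`), `auc`, `auc_ci_95`, `ci_method`,
#'   `p_vs_chance`, `n_pos`, `n_neg`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @export
roc_analysis <- function(x, ...) UseMethod("roc_analysis")

#' @rdname roc_analysis
#' @param labels Vector of class labels aligned with the scores.
#' @param positive Label counted as positive (default `"patient"`).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Seed for the bootstrap.
#' @export
roc_analysis.default <- function(x, labels, positive = "patient",
                                 ci_method = c("delong", "bootstrap"),
                                 n_boot = 2000L, seed = 1L, ...) {
  ci_method <- match.arg(ci_method)
  keep <- !is.na(x) & !is.na(labels)
  scores <- x[keep]
  pos <- as.character(labels[keep]) == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present", class = "cfbrain_input_error")
  }
  auc <- auc_concordance(scores, pos)
  th <- c(sort(unique(scores)), Inf)
  points <- tibble(
    threshold = th,
    sensitivity = vapply(th, function(t) mean(scores[pos] >= t), numeric(1)),
    specificity = vapply(th, function(t) mean(scores[!pos] < t), numeric(1)))
  ci <- if (ci_method == "delong") {
    resp <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
    as.numeric(pROC::ci.auc(pROC::roc(resp, scores, direction = "<",
                                      levels = c("neg", "pos"),
                                      quiet = TRUE),
                            method = "delong"))[c(1L, 3L)]
  } else {
    boot_auc_ci(scores, pos, n_boot, seed)
  }
  p <- mann_whitney.default(scores[pos], scores[!pos])$p_value
  structure(list(points = points, auc = auc, auc_ci_95 = ci,
                 ci_method = ci_method, p_vs_chance = p,
                 n_pos = n1, n_neg = n0, positive = positive),
            class = "cfb_roc")
}

#' @rdname roc_analysis
#' @param score,group Data-frame columns (tidy-eval) holding the score and
#'   the class label.
#' @export
roc_analysis.data.frame <- function(x, score, group, positive = "patient",
                                    ci_method = c("delong", "bootstrap"),
                                    n_boot = 2000L, seed = 1L, ...) {
  roc_analysis.default(pull(x, {{ score }}), pull(x, {{ group }}),
                       positive = positive, ci_method = ci_method,
                       n_boot = n_boot, seed = seed)
}

# Tie-halved concordance AUC via midranks.
auc_concordance <- function(scores, pos) {
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

boot_auc_ci <- function(scores, pos, n_boot, seed) {
  sp <- scores[pos]; sn <- scores[!pos]
  with_seed_if(seed, {
    aucs <- vapply(seq_len(n_boot), function(b) {
      auc_concordance(
        c(sample(sp, replace = TRUE), sample(sn, replace = TRUE)),
        rep(c(TRUE, FALSE), c(length(sp), length(sn))))
    }, numeric(1))
    unname(quantile(aucs, c(0.025, 0.975)))
  })
}

#' @export
print.cfb_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (95%% CI %.3f-%.3f, %s), p vs 0.5 = %.4g, n = %d pos / %d neg\n",
              x$auc, x$auc_ci_95[1], x$auc_ci_95[2], x$ci_method,
              x$p_vs_chance, x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity at a fixed specificity
#'
#' Maximum sensitivity over the empirical thresholds whose specificity is at
#' least the target -- no interpolation, so the answer is conservative and
#' attainable at a real threshold (reported alongside).
#'
#' @param roc A `cfb_roc` object from [roc_analysis()].
#' @param target_specificity Required minimum specificity (default 0.90).
#' @return One-row tibble: `target_specificity`, `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
sensitivity_at_specificity <- function(roc, target_specificity = 0.90) {
  pts <- roc$points[roc$points$specificity >= target_specificity, ,
                    drop = FALSE]
  best <- pts[which.max(pts$sensitivity), , drop = FALSE]
  tibble(target_specificity = target_specificity,
         threshold = best$threshold,
         sensitivity = best$sensitivity,
         specificity = best$specificity)
}

#' Olanzapine-equivalent antipsychotic doses
#'
#' Converts per-drug dose records to a single olanzapine-equivalent dose per
#' sample and time window using expert-consensus equivalence factors
#' (mg olanzapine per mg drug). The shipped default table derives from the
#' international consensus reference doses (olanzapine 20 mg/day); it is
#' plain TSV config data and can be replaced.
#'
#' @param records Tibble with `sample_id`, `drug_name`, `dose_mg`, `when`
#'   (e.g. `day_of_draw`, `cumulative_hospitalization`).
#' @param table Equivalence tibble with `drug` and `factor_mg_olz_per_mg`;
#'   defaults to [olz_equivalents()].
#' @param samples Optional sample ids to complete with 0 mg.
#' @return Tibble `sample_id`, `when`, `olz_eq_mg`.
#' @export
olanzapine_equivalent <- function(records, table = olz_equivalents(),
                                  samples = NULL) {
  if (nrow(records) && any(records$dose_mg < 0, na.rm = TRUE)) {
    abort("negative dose_mg", class = "cfbrain_input_error")
  }
  drug <- tolower(trimws(records$drug_name))
  unknown <- setdiff(unique(drug), tolower(table$drug))
  if (length(unknown)) {
    abort(paste("unknown drug(s) in dose records:",
                paste(unknown, collapse = ", ")),
          class = "cfbrain_input_error")
  }
  fac <- table$factor_mg_olz_per_mg[match(drug, tolower(table$drug))]
  out <- tibble(sample_id = records$sample_id, when = records$when,
                olz = records$dose_mg * fac) |>
    group_by(.data$sample_id, .data$when) |>
    summarise(olz_eq_mg = sum(.data$olz), .groups = "drop")
  if (!is.null(samples)) {
    whens <- unique(c(out$when, "day_of_draw", "cumulative_hospitalization"))
    out <- tidyr::expand_grid(sample_id = samples, when = whens) |>
      left_join(out, by = c("sample_id", "when")) |>
      mutate(olz_eq_mg = tidyr::replace_na(.data$olz_eq_mg, 0))
  }
  out
}

#' @rdname olanzapine_equivalent
#' @export
olz_equivalents <- function() {
  readr::read_tsv(system.file("extdata", "olanzapine_equivalents.tsv",
                              package = "cfbrain"),
                  col_types = "cd", progress = FALSE)
}

#' Drug-dose correlation screen across cfDNA variables
#'
#' For each cfDNA variable (by default the 13 per-marker concentrations,
#' the 4 cell-type averages and total cfDNA = 18 variables) against each
#' dose variable, computes Pearson and Spearman correlations and, for a
#' categorical high/low dose split, Welch t and Mann-Whitney tests.
#' P-values are adjusted across the whole grid (Benjamini-Hochberg by
#' default); nominal and adjusted significance are flagged separately.
#' Cells with fewer than 3 complete pairs or a constant variable are
#' reported missing with a reason.
#'
#' @param cohort Cohort tibble (patients are selected via `group_col`).
#' @param dose_vars Dose column names.
#' @param variables cfDNA variable names; `NULL` selects `ge_`-prefixed
#'   marker columns, the cell-type columns present and
#'   `total_cfdna_ng_per_ml`.
#' @param group_col,patient_level Column and level identifying patients.
#' @param split `"median"` (split doses at the patient median) or a number
#'   used as the threshold.
#' @param adjust_method Passed to [stats::p.adjust()].
#' @param alpha Significance level for the flags.
#' @return Tibble of class `cfb_screen`: `variable`, `dose_var`, `test`,
#'   `estimate`, `p_value`, `p_adjusted`, `significant_nominal`,
#'   `significant_adjusted`, `note`.
#' @export
drug_correlation_screen <- function(cohort,
                                    dose_vars = c("dose_day_olz_eq",
                                                  "dose_cumulative_olz_eq"),
                                    variables = NULL,
                                    group_col = "group",
                                    patient_level = "patient",
                                    split = "median",
                                    adjust_method = "BH",
                                    alpha = 0.05) {
  pats <- cohort[cohort[[group_col]] == patient_level, , drop = FALSE]
  if (is.null(variables)) {
    variables <- c(grep("^ge_", names(cohort), value = TRUE),
                   intersect(c("neuron", "astrocyte", "oligodendrocyte",
                               "whole_brain"), names(cohort)),
                   "total_cfdna_ng_per_ml")
  }
  grid <- tidyr::expand_grid(variable = variables, dose_var = dose_vars)
  res <- purrr::pmap(grid, function(variable, dose_var) {
    v <- pats[[variable]]; d <- pats[[dose_var]]
    ok <- complete.cases(v, d)
    screen_cell(v[ok], d[ok], variable, dose_var, split)
  })
  out <- bind_rows(res)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust_method)
  out$significant_nominal <- !is.na(out$p_value) & out$p_value < alpha
  out$significant_adjusted <- !is.na(out$p_adjusted) & out$p_adjusted < alpha
  class(out) <- c("cfb_screen", class(out))
  out
}

screen_cell <- function(v, d, variable, dose_var, split) {
  base <- tibble(variable = variable, dose_var = dose_var,
                 test = c("pearson", "spearman", "t", "mann_whitney"),
                 estimate = NA_real_, p_value = NA_real_, note = NA_character_)
  if (length(v) < 3L) {
    base$note <- "fewer than 3 complete pairs"
    return(base)
  }
  if (sd(v) == 0 || sd(d) == 0) {
    base$note <- "constant variable"
    return(base)
  }
  pe <- cor.test(v, d, method = "pearson")
  sp <- suppressWarnings(cor.test(v, d, method = "spearman", exact = FALSE))
  base$estimate[1:2] <- c(unname(pe$estimate), unname(sp$estimate))
  base$p_value[1:2] <- c(pe$p.value, sp$p.value)
  thr <- if (identical(split, "median")) median(d) else as.numeric(split)
  hi <- d > thr
  if (sum(hi) >= 2L && sum(!hi) >= 2L &&
      (sd(v[hi]) > 0 || sd(v[!hi]) > 0)) {
    tt <- t.test(v[hi], v[!hi])
    mw <- mann_whitney.default(v[hi], v[!hi])
    base$estimate[3] <- unname(tt$estimate[1] - tt$estimate[2])
    base$p_value[3] <- tt$p.value
    base$estimate[4] <- mw$U / (mw$n_x * mw$n_y)
    base$p_value[4] <- mw$p_value
  } else {
    base$note[3:4] <- "degenerate dose split"
  }
  base
}
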