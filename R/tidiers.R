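#' Tidy a Mann-Whitney result
#'
#' @param x A `cfb_mw` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.cfb_mw <- function(x, ...) {
  tibble(U = x$U, p_value = x$p_value, n_x = x$n_x, n_y = x$n_y,
         exact = x$exact, alternative = x$alternative)
}

#' @rdname tidy.cfb_mw
#' @export
glance.cfb_mw <- function(x, ...) tidy.cfb_mw(x)

#' Tidy ROC results
#'
#' `tidy()` returns the empirical ROC points; `glance()` the one-row AUC
#' summary.
#'
#' @param x A `cfb_roc` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cfb_roc <- function(x, ...) x$points

#' @rdname tidy.cfb_roc
#' @export
glance.cfb_roc <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$auc_ci_95[1], ci_high = x$auc_ci_95[2],
         ci_method = x$ci_method, p_vs_chance = x$p_vs_chance,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy headline cohort statistics
#'
#' `tidy()` returns the per-signal Mann-Whitney table; `glance()` the ROC
#' summary with the sensitivity at the target specificity.
#'
#' @param x A `cfb_headline` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cfb_headline <- function(x, ...) x$group_tests

#' @rdname tidy.cfb_headline
#' @export
glance.cfb_headline <- function(x, ...) {
  bind_cols(glance.cfb_roc(x$roc),
            x$sensitivity[, c("target_specificity", "sensitivity")])
}
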