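#' Plot an empirical ROC curve
#'
#' @param object A `cfb_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cfb_roc <- function(object, ...) {
  pts <- object$points |>
    arrange(dplyr::desc(.data$sensitivity))
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv", linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.2f (95%% CI %.2f-%.2f)",
                                  object$auc, object$auc_ci_95[1],
                                  object$auc_ci_95[2])) +
    ggplot2::theme_minimal()
}

#' Compare per-sample brain cfDNA scores between groups
#'
#' @param cohort Cohort tibble with a `group` column.
#' @param score Score column (tidy-eval; default `combined_brain_score`).
#' @return A ggplot (jittered points with group medians).
#' @export
plot_group_scores <- function(cohort, score = combined_brain_score) {
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$group, y = {{ score }})) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, size = 1.8) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.4, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "Brain cfDNA (genome equivalents / mL)") +
    ggplot2::theme_minimal()
}

#' Plot a dilution series: estimated versus spiked fraction
#'
#' @param dilution Tibble from [dilution_series()].
#' @return A ggplot.
#' @export
plot_dilution <- function(dilution) {
  ggplot2::ggplot(dilution,
                  ggplot2::aes(x = factor(.data$fraction),
                               y = .data$estimated_fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1.2) +
    ggplot2::labs(x = "Spiked brain-DNA fraction",
                  y = "Estimated fully unmethylated fraction") +
    ggplot2::theme_minimal()
}
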