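#' Simulated dilution series through the full read pipeline
#'
#' For each seed and spiked brain-DNA fraction, simulates bisulfite amplicon
#' reads over the whole panel, runs them through quality filtering, amplicon
#' assignment and CpG calling, and reports the pooled estimated fraction of
#' fully unmethylated molecules across all markers. This is the in-silico
#' analogue of serially diluting brain DNA into leukocyte DNA.
#'
#' @param panel Marker panel tibble.
#' @param fractions Spiked fractions; must include 0 for background if
#'   [detection_limit()] is to be applied.
#' @param depth Molecules per marker.
#' @param seeds Integer vector of replicate seeds.
#' @param conversion_rate,inappropriate_rate,seq_error_rate Simulator rates.
#' @param min_mean_q,min_similarity Pipeline thresholds.
#' @return Tibble with `seed`, `fraction`, `n_pass`, `n_fully_unmethylated`,
#'   `estimated_fraction` (pooled over markers).
#' @export
dilution_series <- function(panel,
                            fractions = c(0, 5e-4, 1e-3, 1e-2),
                            depth = 30000L,
                            seeds = 1:10,
                            conversion_rate = 0.99,
                            inappropriate_rate = 0.005,
                            seq_error_rate = 0.001,
                            min_mean_q = 30,
                            min_similarity = 0.8) {
  grid <- tidyr::expand_grid(seed = seeds, fraction = fractions)
  purrr::pmap_dfr(grid, function(seed, fraction) {
    reads <- simulate_reads(panel, depth, fraction,
                            conversion_rate = conversion_rate,
                            inappropriate_rate = inappropriate_rate,
                            seq_error_rate = seq_error_rate,
                            sample_id = "dilution",
                            seed = seed + round(1e6 * fraction))
    calls <- process_reads(reads, panel, min_mean_q = min_mean_q,
                           min_similarity = min_similarity)
    pass <- calls[calls$status == "pass", , drop = FALSE]
    n_unmeth <- sum(grepl("^T+$", pass$pattern))
    tibble(seed = seed, fraction = fraction, n_pass = nrow(pass),
           n_fully_unmethylated = n_unmeth,
           estimated_fraction = n_unmeth / nrow(pass))
  })
}

#' Detection limit of a dilution series
#'
#' The smallest nonzero spiked fraction whose pooled estimated fraction
#' strictly exceeds the zero-spike background of the same seed in at least
#' `min_seeds` of the replicates.
#'
#' @param dilution Tibble from [dilution_series()] (must include
#'   `fraction == 0` rows).
#' @param min_seeds Minimum number of detecting replicates.
#' @return List with `per_fraction` (tibble `fraction`, `n_detected`,
#'   `n_seeds`, `detected`), `limit_fraction` and `limit_percent`
#'   (`NA` if nothing qualifies).
#' @export
detection_limit <- function(dilution, min_seeds = 9L) {
  bg <- dilution |>
    filter(.data$fraction == 0) |>
    select("seed", bg_fraction = "estimated_fraction")
  per <- dilution |>
    filter(.data$fraction > 0) |>
    inner_join(bg, by = "seed") |>
    group_by(.data$fraction) |>
    summarise(n_detected = sum(.data$estimated_fraction > .data$bg_fraction),
              n_seeds = dplyr::n(), .groups = "drop") |>
    mutate(detected = .data$n_detected >= min_seeds)
  hit <- per$fraction[per$detected]
  limit <- if (length(hit)) min(hit) else NA_real_
  list(per_fraction = per, limit_fraction = limit,
       limit_percent = 100 * limit)
}
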