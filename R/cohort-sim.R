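#' Simulate a case/control cfDNA cohort
#'
#' Draws per-sample brain-derived genome equivalents (GE/mL, lognormal per
#' cell type) and total cfDNA concentrations per group, converts them into
#' per-marker fractions of fully unmethylated molecules via each sample's
#' total genome concentration, and produces either:
#'
#' * `mode = "counts"` (default): per-marker passing-molecule counts drawn
#'   directly from the binomial sampling model, quantified into a cohort
#'   table -- statistically equivalent to sequencing error-free reads and
#'   fast enough for replicated calibration studies; or
#' * `mode = "reads"`: per-sample FASTQ files written to `out_dir` through
#'   the full bisulfite-read simulator, with a metadata table and truth
#'   tables, for end-to-end pipeline runs.
#'
#' Whole-brain markers see the summed signal of all three cell types.
#' Patients receive simulated antipsychotic dose records (olanzapine
#' equivalents), independent of the cfDNA signal unless `dose_association`
#' is positive.
#'
#' @param panel Marker panel tibble.
#' @param n_cases,n_controls Group sizes.
#' @param mode `"counts"` or `"reads"`.
#' @param depth Passing molecules per marker per sample.
#' @param control_brain_ge Lognormal parameters (`meanlog`, `sdlog`) of the
#'   per-cell-type brain signal in controls (GE/mL).
#' @param case_brain_multiplier Multiplicative shift of the case brain
#'   signal (1 = null cohort).
#' @param total_cfdna List with `control` and `case` lognormal parameters
#'   for total cfDNA (ng/mL).
#' @param pg_per_haploid_genome Genome mass constant (pg).
#' @param conversion_rate,inappropriate_rate,seq_error_rate Read-simulator
#'   rates (used in `"reads"` mode).
#' @param dose_association Standardised log-linear dependence of dose on the
#'   true brain signal (0 = independent).
#' @param out_dir Output directory for `"reads"` mode.
#' @param seed Optional integer seed.
#' @return In counts mode, a cohort tibble (as [cohort_table()]) with the
#'   per-sample ground truth in attribute `truth`. In reads mode, a list
#'   with `metadata` (including per-sample `fastq` paths and barcodes),
#'   `truth`, and `dir`.
#' @export
simulate_cohort <- function(panel, n_cases = 29L, n_controls = 31L,
                            mode = c("counts", "reads"),
                            depth = 30000L,
                            control_brain_ge = list(meanlog = log(2),
                                                    sdlog = 0.5),
                            case_brain_multiplier = 2,
                            total_cfdna = list(
                              control = list(meanlog = log(7), sdlog = 0.4),
                              case = list(meanlog = log(9), sdlog = 0.4)),
                            pg_per_haploid_genome = 3.3,
                            conversion_rate = 0.99,
                            inappropriate_rate = 0.005,
                            seq_error_rate = 0.001,
                            dose_association = 0,
                            out_dir = NULL,
                            seed = NULL) {
  mode <- match.arg(mode)
  n_cases <- assert_count(n_cases, "n_cases")
  n_controls <- assert_count(n_controls, "n_controls")
  depth <- assert_count(depth, "depth")
  check_lnorm(control_brain_ge, "control_brain_ge")
  check_lnorm(total_cfdna$control, "total_cfdna$control")
  check_lnorm(total_cfdna$case, "total_cfdna$case")
  if (!is_scalar_number(case_brain_multiplier) || case_brain_multiplier <= 0) {
    abort("case_brain_multiplier must be positive",
          class = "cfbrain_config_error")
  }
  cell_types <- c("neuron", "astrocyte", "oligodendrocyte")

  with_seed_if(seed, {
    n <- n_cases + n_controls
    group <- rep(c("patient", "control"), c(n_cases, n_controls))
    sample_id <- sprintf("%s_%02d", ifelse(group == "patient", "case", "ctrl"),
                         c(seq_len(n_cases), seq_len(n_controls)))
    ge <- matrix(rlnorm(n * 3L, control_brain_ge$meanlog,
                        control_brain_ge$sdlog),
                 nrow = n, dimnames = list(NULL, cell_types))
    ge[group == "patient", ] <- ge[group == "patient", ] * case_brain_multiplier
    cf <- numeric(n)
    cf[group == "control"] <- rlnorm(n_controls, total_cfdna$control$meanlog,
                                     total_cfdna$control$sdlog)
    cf[group == "patient"] <- rlnorm(n_cases, total_cfdna$case$meanlog,
                                     total_cfdna$case$sdlog)
    total_ge <- cf * 1000 / pg_per_haploid_genome
    brain_sum <- rowSums(ge)
    marker_f <- vapply(seq_len(nrow(panel)), function(j) {
      ct <- panel$cell_type[j]
      sig <- if (ct %in% cell_types) ge[, ct] else brain_sum
      pmin(sig / total_ge, 1)
    }, numeric(n))
    colnames(marker_f) <- panel$marker_id

    age <- round(rnorm(n, 26, 5))
    sex <- sample(c("M", "F"), n, replace = TRUE)
    dose_day <- rep(NA_real_, n)
    pat <- group == "patient"
    z <- as.numeric(scale(log(brain_sum[pat])))
    dose_day[pat] <- rlnorm(n_cases, log(10) + dose_association * z, 0.6)
    days <- runif(n_cases, 7, 60)
    dose_cum <- rep(NA_real_, n)
    dose_cum[pat] <- dose_day[pat] * days
    metadata <- tibble(sample_id = sample_id, group = group, age = age,
                       sex = sex, total_cfdna_ng_per_ml = cf,
                       dose_day_olz_eq = dose_day,
                       dose_cumulative_olz_eq = dose_cum)
    truth <- bind_cols(tibble(sample_id = sample_id, group = group),
                       as_tibble(ge),
                       tibble(true_combined = brain_sum,
                              total_cfdna_ng_per_ml = cf))

    if (mode == "counts") {
      mq <- tidyr::expand_grid(i = seq_len(n), j = seq_len(nrow(panel))) |>
        mutate(sample_id = sample_id[.data$i],
               marker_id = panel$marker_id[.data$j],
               cell_type = panel$cell_type[.data$j],
               n_pass = depth,
               n_fully_unmethylated = rbinom(dplyr::n(), depth,
                                             marker_f[cbind(.data$i, .data$j)]),
               fraction = .data$n_fully_unmethylated / .data$n_pass,
               total_cfdna_ng_per_ml = cf[.data$i],
               ge_per_ml = genome_equivalents_per_ml(
                 .data$fraction, .data$total_cfdna_ng_per_ml,
                 pg_per_haploid_genome)) |>
        select(-"i", -"j")
      cohort <- cohort_table(mq, metadata)
      attr(cohort, "truth") <- truth
      attr(cohort, "marker_quant") <- mq
      return(cohort)
    }

    if (is.null(out_dir)) {
      abort("reads mode needs out_dir", class = "cfbrain_config_error")
    }
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    barcodes <- make_barcodes(n)
    metadata$barcode <- barcodes
    metadata$fastq <- file.path(out_dir, paste0(sample_id, ".fastq"))
    for (i in seq_len(n)) {
      reads <- simulate_reads(panel, depth,
                              target_fraction = marker_f[i, ],
                              conversion_rate = conversion_rate,
                              inappropriate_rate = inappropriate_rate,
                              seq_error_rate = seq_error_rate,
                              sample_id = sample_id[i], seed = NULL)
      emit_fastq(reads, metadata$fastq[i],
                 barcode_map = setNames(barcodes[i], sample_id[i]),
                 truth_path = file.path(out_dir,
                                        paste0(sample_id[i], ".truth.tsv")))
    }
    readr::write_tsv(metadata, file.path(out_dir, "metadata.tsv"), na = ".")
    readr::write_tsv(truth, file.path(out_dir, "truth.tsv"), na = ".")
    list(metadata = metadata, truth = truth, dir = out_dir)
  })
}

check_lnorm <- function(x, name) {
  if (!is.list(x) || !is_scalar_number(x$meanlog %||% NA) ||
      !is_scalar_number(x$sdlog %||% NA) || x$sdlog <= 0) {
    abort(sprintf("`%s` must be list(meanlog = , sdlog = ) with sdlog > 0",
                  name), class = "cfbrain_config_error")
  }
  invisible(x)
}

# Distinct 8-mer barcodes, deterministic under the ambient RNG.
make_barcodes <- function(n, width = 8L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
                  collapse = "")
    if (!cand %in% out) out <- c(out, cand)
  }
  out
}
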