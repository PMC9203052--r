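#' Select loci specifically unmethylated in one cell class
#'
#' Scans a beta-value matrix for loci that are unmethylated in every sample
#' of the target class (max beta over target samples <= `t_low`) and
#' methylated in every sample of every other class (min beta over background
#' samples >= `t_high`) -- a worst-case ("all samples") reading of
#' cell-type specificity. Candidates are ranked by descending margin
#' (background min minus target max). Loci with any missing beta in a
#' deciding group are excluded and reported via the `excluded` attribute.
#'
#' @param beta Tibble with a `locus` column and one numeric column per
#'   sample, values in \[0, 1\] or `NA`.
#' @param labels Tibble with columns `sample` and `label` covering every
#'   sample column of `beta`.
#' @param target_label Label (or vector of labels treated as one group)
#'   whose samples must be unmethylated.
#' @param t_low Upper bound on target-class beta (default 0.2).
#' @param t_high Lower bound on background-class beta (default 0.8).
#' @return Tibble with `locus`, `target_label`, `target_max_beta`,
#'   `background_min_beta`, `margin`, ranked by descending margin.
#' @export
select_specific_loci <- function(beta, labels, target_label,
                                 t_low = 0.2, t_high = 0.8) {
  bm <- beta_as_matrix(beta, labels)
  if (!all(target_label %in% unique(bm$labels))) {
    abort(paste("unknown target label:",
                paste(setdiff(target_label, bm$labels), collapse = ", ")),
          class = "cfbrain_input_error")
  }
  if (length(unique(bm$labels)) < 2L || all(bm$labels %in% target_label)) {
    abort("beta matrix must contain at least one non-target label",
          class = "cfbrain_input_error")
  }
  if (t_low >= t_high) {
    abort("t_low must be below t_high", class = "cfbrain_config_error")
  }
  tcols <- bm$labels %in% target_label
  tmax <- apply(bm$m[, tcols, drop = FALSE], 1L, max)
  bmin <- apply(bm$m[, !tcols, drop = FALSE], 1L, min)
  incomplete <- is.na(tmax) | is.na(bmin)
  hit <- !incomplete & tmax <= t_low & bmin >= t_high
  out <- tibble(locus = bm$loci[hit],
                target_label = paste(target_label, collapse = "+"),
                target_max_beta = tmax[hit],
                background_min_beta = bmin[hit],
                margin = bmin[hit] - tmax[hit]) |>
    arrange(dplyr::desc(.data$margin))
  attr(out, "excluded") <- bm$loci[incomplete]
  if (any(incomplete)) {
    inform(sprintf("%d loci excluded for missing beta values in a deciding group",
                   sum(incomplete)))
  }
  out
}

beta_as_matrix <- function(beta, labels) {
  if (!"locus" %in% names(beta)) {
    abort("`beta` needs a `locus` column", class = "cfbrain_input_error")
  }
  if (!all(c("sample", "label") %in% names(labels))) {
    abort("`labels` needs `sample` and `label` columns",
          class = "cfbrain_input_error")
  }
  samples <- setdiff(names(beta), c("locus", "chrom", "start", "end"))
  unlabeled <- setdiff(samples, labels$sample)
  if (length(unlabeled)) {
    abort(paste("samples without label:", paste(unlabeled, collapse = ", ")),
          class = "cfbrain_input_error")
  }
  m <- as.matrix(beta[samples])
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]", class = "cfbrain_input_error")
  }
  lv <- labels$label[match(samples, labels$sample)]
  list(m = m, loci = beta$locus, labels = lv)
}

#' Classify selected loci into cell-type and whole-brain marker classes
#'
#' Whole-brain candidates are loci unmethylated across the union of the
#' brain cell labels and methylated elsewhere; per-cell-type candidates are
#' loci specific to a single brain label. A locus is assigned to the most
#' specific class, so whole-brain hits are removed from the per-cell-type
#' lists.
#'
#' @inheritParams select_specific_loci
#' @param cell_labels Character vector of brain cell labels (each must be a
#'   distinct label of `labels`).
#' @param whole_brain_label Name given to the union class.
#' @return Tibble of candidates with a `cell_type` column (one of
#'   `cell_labels` or `whole_brain_label`), a panel skeleton ready for
#'   amplicon design. Empty (with a warning) when nothing passes.
#' @export
build_marker_classes <- function(beta, labels,
                                 cell_labels = c("neuron", "astrocyte",
                                                 "oligodendrocyte"),
                                 whole_brain_label = "whole_brain",
                                 t_low = 0.2, t_high = 0.8) {
  if (anyDuplicated(cell_labels) || whole_brain_label %in% cell_labels) {
    abort("overlapping label definitions", class = "cfbrain_config_error")
  }
  wb <- select_specific_loci(beta, labels, cell_labels, t_low, t_high) |>
    mutate(cell_type = whole_brain_label)
  per_type <- purrr::map(cell_labels, function(lb) {
    select_specific_loci(beta, labels, lb, t_low, t_high) |>
      filter(!.data$locus %in% wb$locus) |>
      mutate(cell_type = lb)
  })
  out <- bind_rows(c(per_type, list(wb))) |>
    select("locus", "cell_type", "target_label", "target_max_beta",
           "background_min_beta", "margin")
  if (nrow(out) == 0L) {
    warn("no locus passed any marker class")
  }
  out
}

#' Simulate a reference beta-value matrix with planted markers
#'
#' Background loci are methylated everywhere (beta ~ Beta(90, 10), mean 0.9).
#' Planted marker loci are unmethylated (beta ~ Beta(2, 38), mean 0.05) in
#' the samples of their target class -- a single cell label, or all brain
#' labels for whole-brain markers -- and methylated elsewhere.
#'
#' @param n_loci Total number of loci.
#' @param n_planted Named integer vector: markers to plant per class; use
#'   `whole_brain` for the union class.
#' @param samples_per_label Named integer vector: reference samples per
#'   label. Non-brain labels (e.g. leukocyte tissues) form the background.
#' @param brain_labels Labels making up the whole-brain union.
#' @param seed Integer seed.
#' @return List with `beta` (tibble, `locus` + sample columns), `labels`
#'   (tibble `sample`, `label`) and `truth` (tibble `locus`, `cell_type` of
#'   planted markers).
#' @export
simulate_beta_matrix <- function(n_loci = 200L,
                                 n_planted = c(neuron = 4, astrocyte = 3,
                                               oligodendrocyte = 3,
                                               whole_brain = 3),
                                 samples_per_label = c(neuron = 3,
                                                       astrocyte = 3,
                                                       oligodendrocyte = 3,
                                                       leukocyte = 5,
                                                       hepatocyte = 3),
                                 brain_labels = c("neuron", "astrocyte",
                                                  "oligodendrocyte"),
                                 seed = 1L) {
  with_seed_if(seed, {
    labels <- tibble(
      sample = unlist(purrr::imap(as.list(samples_per_label), function(n, lb)
        sprintf("%s_%d", lb, seq_len(n)))),
      label = rep(names(samples_per_label), times = samples_per_label))
    n_samp <- nrow(labels)
    m <- matrix(rbeta(n_loci * n_samp, 90, 10), nrow = n_loci)
    loci <- sprintf("cg%06d", seq_len(n_loci))
    planted_ct <- rep(names(n_planted), times = n_planted)
    if (length(planted_ct) > n_loci) {
      abort("more planted markers than loci", class = "cfbrain_config_error")
    }
    planted_rows <- sample(n_loci, length(planted_ct))
    for (i in seq_along(planted_ct)) {
      target <- if (planted_ct[i] == "whole_brain") brain_labels else planted_ct[i]
      cols <- labels$label %in% target
      m[planted_rows[i], cols] <- rbeta(sum(cols), 2, 38)
    }
    beta <- bind_cols(tibble(locus = loci),
                      as_tibble(`colnames<-`(m, labels$sample)))
    truth <- tibble(locus = loci[planted_rows], cell_type = planted_ct) |>
      arrange(.data$locus)
    list(beta = beta, labels = labels, truth = truth)
  })
}
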