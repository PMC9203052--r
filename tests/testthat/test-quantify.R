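mini_panel <- function() {
  tibble::tibble(
    marker_id = c("n1", "n2", "n3", "n4", "a1", "o1", "w1"),
    cell_type = c("neuron", "neuron", "neuron", "neuron", "astrocyte",
                  "oligodendrocyte", "whole_brain"),
    sequence = "ACGTT", cpg_pos = list(2L))
}

calls_tbl <- function(marker_id, n_total, n_unmeth, sample_id = "s1") {
  tibble::tibble(
    read_id = sprintf("%s_r%d", marker_id, seq_len(n_total)),
    sample_id = sample_id, marker_id = marker_id, similarity = 1,
    pattern = rep(c("T", "C"), c(n_unmeth, n_total - n_unmeth)),
    status = "pass")
}

test_that("fully unmethylated fraction counts only all-T molecules", {
  panel <- mini_panel()[1, ]
  f <- fraction_fully_unmethylated(calls_tbl("n1", 1000, 1), panel)
  expect_equal(f$fraction, 0.001)
  expect_equal(fraction_fully_unmethylated(calls_tbl("n1", 50, 0), panel)$fraction, 0)
  # a molecule with one methylated CpG among unmethylated ones does not count
  mixed <- tibble::tibble(read_id = sprintf("r%d", 1:11), sample_id = "s1",
                          marker_id = "n1", similarity = 1,
                          pattern = c("TTTC", rep("CCCC", 10)),
                          status = "pass")
  expect_equal(fraction_fully_unmethylated(mixed, panel)$fraction, 0)
  # non-pass molecules are ignored entirely
  spiked <- dplyr::mutate(calls_tbl("n1", 10, 0),
                          status = rep(c("pass", "fail_similarity"), 5))
  expect_equal(fraction_fully_unmethylated(spiked, panel)$n_pass, 5L)
})

test_that("zero-coverage markers become missing with a warning, never zero", {
  panel <- mini_panel()[1:2, ]
  expect_warning(f <- fraction_fully_unmethylated(calls_tbl("n1", 10, 1), panel),
                 "zero passing")
  expect_equal(f$n_pass[f$marker_id == "n2"], 0L)
  expect_true(is.na(f$fraction[f$marker_id == "n2"]))
})

test_that("genome equivalents follow fraction x ng/mL x 1000 / pg-per-genome", {
  expect_equal(genome_equivalents_per_ml(0, 12), 0)
  expect_equal(genome_equivalents_per_ml(0.001, 3.3), 1)
  expect_equal(genome_equivalents_per_ml(1, 3.3), 1000)
  expect_equal(genome_equivalents_per_ml(0.5, 10, pg_per_haploid_genome = 5),
               1000)
  expect_error(genome_equivalents_per_ml(-0.1, 1),
               class = "cfbrain_input_error")
  expect_error(genome_equivalents_per_ml(0.5, -1),
               class = "cfbrain_input_error")
})

test_that("cell-type aggregation averages markers and sums the three cell classes", {
  panel <- mini_panel()
  meta <- tibble::tibble(sample_id = "s1", total_cfdna_ng_per_ml = 3.3)
  # fractions chosen so ge_per_ml are neuron 2,2,2,2; astro 1; oligo 0.5; wb 9
  fr <- c(n1 = 0.002, n2 = 0.002, n3 = 0.002, n4 = 0.002,
          a1 = 0.001, o1 = 0.0005, w1 = 0.009)
  calls <- dplyr::bind_rows(purrr::imap(as.list(fr), function(f, id)
    calls_tbl(id, 10000, round(10000 * f))))
  mq <- quantify_markers(calls, meta, panel)
  ct <- aggregate_cell_types(mq)
  expect_equal(ct$mean_ge_per_ml[ct$cell_type == "neuron"], 2)
  summ <- sample_summary(mq)
  expect_equal(summ$combined_brain_score, 2 + 1 + 0.5)
  expect_equal(summ$whole_brain, 9)
  with_wb <- sample_summary(mq, include_whole_brain = TRUE)
  expect_equal(with_wb$combined_brain_score, 12.5)
  # fraction-based aggregate mirrors the concentrations without the scaling
  expect_equal(summ$combined_fraction_score, 0.002 + 0.001 + 0.0005)
})

test_that("a cell type with no covered markers silences the combined score", {
  panel <- mini_panel()
  meta <- tibble::tibble(sample_id = "s1", total_cfdna_ng_per_ml = 3.3)
  calls <- dplyr::bind_rows(purrr::map(c("n1", "n2", "n3", "n4", "o1", "w1"),
                                       ~calls_tbl(.x, 100, 1)))
  suppressWarnings(mq <- quantify_markers(calls, meta, panel))
  summ <- sample_summary(mq)
  expect_true(is.na(summ$astrocyte))
  expect_true(is.na(summ$combined_brain_score))
})

test_that("scores scale with total cfDNA while fractions do not", {
  panel <- mini_panel()
  calls <- dplyr::bind_rows(purrr::map(panel$marker_id, ~calls_tbl(.x, 1000, 5)))
  m1 <- quantify_markers(calls, tibble::tibble(sample_id = "s1",
                                               total_cfdna_ng_per_ml = 4), panel)
  m2 <- quantify_markers(calls, tibble::tibble(sample_id = "s1",
                                               total_cfdna_ng_per_ml = 8), panel)
  expect_equal(m2$ge_per_ml, 2 * m1$ge_per_ml)
  expect_equal(m2$fraction, m1$fraction)
  expect_equal(sample_summary(m2)$combined_brain_score,
               2 * sample_summary(m1)$combined_brain_score)
  expect_equal(sample_summary(m2)$combined_fraction_score,
               sample_summary(m1)$combined_fraction_score)
})

test_that("random 75 percent thinning leaves the estimated fraction unbiased", {
  panel <- tiny_panel()
  diffs <- vapply(1:50, function(s) {
    mol <- simulate_molecules(panel, 4000, 0.01, seed = s)
    calls <- calls_from_molecules(mol)
    full <- fraction_fully_unmethylated(calls, panel)
    thin <- fraction_fully_unmethylated(thin_calls(calls, 0.25, seed = s + 1000),
                                        panel)
    mean(thin$fraction) - mean(full$fraction)
  }, numeric(1))
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})
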