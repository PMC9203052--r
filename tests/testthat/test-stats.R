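test_that("Mann-Whitney matches the enumeration oracle on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_true(mw$exact)
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- rnorm(sample(2:8, 1))
      y <- rnorm(sample(2:8, 1))
      expect_equal(mann_whitney(x, y)$p_value, mw_enum_p(x, y))
    }
  })
  # identical samples: p = 1
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # ties force the corrected normal approximation
  tied <- mann_whitney(c(1, 2, 2), c(2, 3, 4))
  expect_false(tied$exact)
  expect_error(mann_whitney(numeric(0), 1:3), class = "cfbrain_input_error")
})

test_that("the data-frame interface reproduces the vector interface", {
  d <- tibble::tibble(v = c(1, 2, 3, 4, 5, 6),
                      g = rep(c("a", "b"), each = 3))
  expect_equal(tidy(mann_whitney(d, v, g))$p_value,
               mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value)
})

test_that("AUC equals the Mann-Whitney concordance and the all-pairs oracle", {
  r <- roc_analysis(c(1, 2, 1.5, 3), c("c", "c", "p", "p"), positive = "p")
  expect_equal(r$auc, 0.75)
  perfect <- roc_analysis(c(1, 1, 2, 2), rep(c("control", "patient"), each = 2))
  expect_equal(perfect$auc, 1)
  withr::with_seed(42, {
    for (i in 1:30) {
      n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
      scores <- round(c(rnorm(n1, 1), rnorm(n0)), sample(c(0, 1, 3), 1))
      labels <- rep(c("patient", "control"), c(n1, n0))
      r <- roc_analysis(scores, labels)
      expect_equal(r$auc, auc_pairs(scores, labels == "patient"))
      mw <- mann_whitney(scores[labels == "patient"],
                         scores[labels == "control"])
      expect_equal(r$auc, mw$U / (n1 * n0))
      expect_equal(r$p_vs_chance, mw$p_value)
    }
  })
  expect_error(roc_analysis(1:4, rep("control", 4)),
               class = "cfbrain_input_error")
})

test_that("DeLong and bootstrap intervals bracket the AUC and respect the seed", {
  withr::with_seed(2, {
    scores <- c(rnorm(20, 1), rnorm(25))
    labels <- rep(c("patient", "control"), c(20, 25))
  })
  d <- roc_analysis(scores, labels)
  expect_true(d$auc_ci_95[1] <= d$auc && d$auc <= d$auc_ci_95[2])
  b1 <- roc_analysis(scores, labels, ci_method = "bootstrap", n_boot = 300,
                     seed = 5)
  b2 <- roc_analysis(scores, labels, ci_method = "bootstrap", n_boot = 300,
                     seed = 5)
  expect_identical(b1$auc_ci_95, b2$auc_ci_95)
  expect_true(b1$auc_ci_95[1] < d$auc & d$auc < b1$auc_ci_95[2])
})

test_that("rank statistics are invariant to monotone rescaling of scores", {
  withr::with_seed(3, {
    scores <- rlnorm(40)
    labels <- rep(c("patient", "control"), 20)
  })
  a <- roc_analysis(scores, labels)
  b <- roc_analysis(exp(scores / 2), labels)
  expect_equal(a$auc, b$auc)
  expect_equal(sensitivity_at_specificity(a, 0.9)$sensitivity,
               sensitivity_at_specificity(b, 0.9)$sensitivity)
  expect_equal(a$p_vs_chance, b$p_vs_chance)
})

test_that("sensitivity at fixed specificity uses attainable thresholds only", {
  perfect <- roc_analysis(c(1, 2, 10, 20), rep(c("control", "patient"), each = 2))
  expect_equal(sensitivity_at_specificity(perfect, 0.9)$sensitivity, 1)
  flat <- roc_analysis(rep(1, 10), rep(c("control", "patient"), 5))
  s <- sensitivity_at_specificity(flat, 0.9)
  expect_equal(s$sensitivity, 0)
  expect_equal(s$specificity, 1)
  # reported threshold really achieves the reported operating point
  withr::with_seed(9, {
    scores <- rnorm(60)
    labels <- rep(c("patient", "control"), 30)
  })
  r <- roc_analysis(scores, labels)
  s <- sensitivity_at_specificity(r, 0.9)
  pos <- scores[labels == "patient"]; neg <- scores[labels == "control"]
  expect_equal(s$sensitivity, mean(pos >= s$threshold))
  expect_gte(mean(neg < s$threshold), 0.9)
})

test_that("olanzapine equivalents are linear in dose with consensus factors", {
  tab <- olz_equivalents()
  expect_true(all(c("olanzapine", "risperidone", "haloperidol") %in% tab$drug))
  expect_equal(tab$factor_mg_olz_per_mg[tab$drug == "olanzapine"], 1)
  rec <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    drug_name = c("olanzapine", "risperidone", "Haloperidol"),
    dose_mg = c(10, 3, 5),
    when = "day_of_draw")
  out <- olanzapine_equivalent(rec)
  f_r <- tab$factor_mg_olz_per_mg[tab$drug == "risperidone"]
  f_h <- tab$factor_mg_olz_per_mg[tab$drug == "haloperidol"]
  expect_equal(out$olz_eq_mg[out$sample_id == "s1"], 10 * 1 + 3 * f_r)
  expect_equal(out$olz_eq_mg[out$sample_id == "s2"], 5 * f_h)
  # empty record sets give 0 mg when samples are supplied
  none <- olanzapine_equivalent(rec[0, ], samples = c("s9"))
  expect_true(all(none$olz_eq_mg == 0))
  expect_error(olanzapine_equivalent(
    tibble::tibble(sample_id = "s1", drug_name = "unobtainium",
                   dose_mg = 1, when = "day_of_draw")),
    "unobtainium", class = "cfbrain_input_error")
  expect_error(olanzapine_equivalent(dplyr::mutate(rec, dose_mg = -1)),
               class = "cfbrain_input_error")
})

test_that("the drug screen spans 18 variables x 2 dose windows x 4 tests", {
  panel <- generate_marker_panel(seed = 42)
  coh <- simulate_cohort(panel, seed = 30)
  scr <- drug_correlation_screen(coh)
  expect_equal(nrow(scr), 18 * 2 * 4)
  expect_equal(length(unique(scr$variable)), 18)
  expect_s3_class(scr, "cfb_screen")
  # BH adjustment is applied over the whole grid
  expect_equal(scr$p_adjusted,
               stats::p.adjust(scr$p_value, "BH"))
})

test_that("the screen flags perfect dependence and degenerate doses", {
  panel <- generate_marker_panel(seed = 42)
  coh <- simulate_cohort(panel, n_cases = 15, n_controls = 5, seed = 8)
  coh$dose_day_olz_eq[coh$group == "patient"] <-
    coh$ge_neuron_01[coh$group == "patient"]
  scr <- drug_correlation_screen(coh, dose_vars = "dose_day_olz_eq")
  hit <- scr[scr$variable == "ge_neuron_01" & scr$test == "spearman", ]
  expect_equal(hit$estimate, 1)
  expect_true(hit$p_value < 1e-6)
  coh$dose_day_olz_eq[coh$group == "patient"] <- 5
  scr2 <- drug_correlation_screen(coh, dose_vars = "dose_day_olz_eq")
  expect_true(all(is.na(scr2$p_value)))
  expect_true(all(scr2$note == "constant variable"))
})
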