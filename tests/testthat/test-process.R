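test_that("demultiplexing assigns by exact barcode and conserves reads", {
  bc <- c(s1 = "AAAACCCC", s2 = "GGGGTTTT")
  reads <- tibble::tibble(
    read_id = c("r1:AAAACCCC", "r2:GGGGTTTT", "r3:AAAATTTT", "r4:AAAACCCC"),
    sequence = c("ACGT", "ACGT", "ACGT", "TTTT"),
    quality = c("IIII", "IIII", "IIII", "IIII"))
  out <- demultiplex(reads, bc)
  expect_equal(out$sample_id, c("s1", "s2", NA, "s1"))
  counts <- attr(out, "demux_counts")
  expect_equal(sum(counts), nrow(reads))
  expect_equal(unname(counts[c("s1", "s2", "unassigned")]), c(2L, 1L, 1L),
               ignore_attr = TRUE)
  # one mismatch allowed recovers r3 (distance 4 to s2 but 4 to s1? no: AAAATTTT
  # is 4 from both, stays unassigned; a 1-off barcode is recovered)
  reads2 <- tibble::tibble(read_id = "r5:AAAACCCA", sequence = "ACGT",
                           quality = "IIII")
  expect_true(is.na(demultiplex(reads2, bc)$sample_id))
  expect_equal(demultiplex(reads2, bc, max_mismatch = 1)$sample_id, "s1")
  expect_error(demultiplex(reads, c(s1 = "AAAACCCC", s2 = "AAAACCCC")),
               class = "cfbrain_config_error")
})

test_that("prefix-mode demultiplexing strips the barcode from sequence and quality", {
  bc <- c(s1 = "ACGTACGT")
  reads <- tibble::tibble(read_id = "r1",
                          sequence = "ACGTACGTTTGGA",
                          quality = "IIIIIIIIFFFFF")
  out <- demultiplex(reads, bc, barcode_mode = "prefix")
  expect_equal(out$sample_id, "s1")
  expect_equal(out$sequence, "TTGGA")
  expect_equal(out$quality, "FFFFF")
})

test_that("quality filter applies the mean-Phred rule with a pass-at-boundary convention", {
  q37 <- strrep(rawToChar(as.raw(37 + 33)), 50)
  q2 <- strrep(rawToChar(as.raw(2 + 33)), 50)
  q30 <- strrep(rawToChar(as.raw(30 + 33)), 50)
  reads <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                          sequence = strrep("A", c(50, 50, 50, 0)),
                          quality = c(q37, q2, q30, ""))
  out <- quality_filter(reads, min_mean_q = 30)
  expect_equal(out$pass_quality, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$mean_q[1:3], c(37, 2, 30))
  # monotonicity: raising the threshold never increases the pass count
  thresholds <- c(0, 10, 20, 30, 37, 40)
  passes <- vapply(thresholds,
                   function(t) sum(quality_filter(reads, t)$pass_quality),
                   numeric(1))
  expect_true(all(diff(passes) <= 0))
})

test_that("edit distance agrees with base adist and honours Y ambiguity", {
  withr::with_seed(8, {
    for (i in 1:30) {
      a <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1), TRUE),
                 collapse = "")
      expect_equal(cfbrain:::cpp_edit_distance(a, b),
                   as.integer(utils::adist(a, b)))
    }
  })
  expect_equal(cfbrain:::cpp_edit_distance("ACA", "AYA"), 0L)
  expect_equal(cfbrain:::cpp_edit_distance("ATA", "AYA"), 0L)
  expect_equal(cfbrain:::cpp_edit_distance("AGA", "AYA"), 1L)
  # Y-aware distances cross-checked against a global pairwise alignment with
  # an explicit ambiguity-aware substitution matrix (unit gap costs)
  lv <- c("A", "C", "G", "T", "Y")
  sm <- matrix(-1L, 5, 5, dimnames = list(lv, lv))
  diag(sm) <- 0L
  sm["C", "Y"] <- sm["Y", "C"] <- sm["T", "Y"] <- sm["Y", "T"] <- 0L
  pa_dist <- function(a, b) {
    -Biostrings::score(Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 1))
  }
  panel <- tiny_panel()
  targets <- converted_targets(panel)
  withr::with_seed(23, {
    for (i in 1:10) {
      t <- sample(targets, 1)
      read <- chartr("Y", sample(c("C", "T"), 1), t)
      ch <- strsplit(read, "")[[1]]
      hit <- sample(length(ch), sample(0:6, 1))
      ch[hit] <- sample(c("A", "C", "G", "T"), length(hit), TRUE)
      if (runif(1) < 0.5) ch <- ch[-sample(length(ch), 1)]  # an indel too
      read <- paste(ch, collapse = "")
      expect_equal(cfbrain:::cpp_edit_distance(read, unname(t)),
                   pa_dist(read, unname(t)))
    }
  })
})

test_that("error-free reads match their own amplicon at high similarity, independent of methylation", {
  panel <- tiny_panel()
  reads <- simulate_reads(panel, 200, 0.5, conversion_rate = 1,
                          inappropriate_rate = 0, seq_error_rate = 0,
                          seed = 4)
  m <- match_to_amplicon(reads, panel)
  expect_identical(m$marker_id, reads$marker_id)
  expect_true(all(m$similarity == 1))
  # methylated and unmethylated molecules of one marker: identical similarity
  one <- panel[1, ]
  pats <- c(strrep("M", length(one$cpg_pos[[1]])),
            strrep("U", length(one$cpg_pos[[1]])))
  seqs <- bisulfite_convert(one$sequence, one$cpg_pos[[1]], pats, 1, 0)
  both <- tibble::tibble(read_id = c("m", "u"), sequence = seqs,
                         quality = strrep("F", nchar(seqs)))
  mm <- match_to_amplicon(both, panel)
  expect_equal(mm$similarity[1], mm$similarity[2])
  expect_equal(mm$marker_id, rep(one$marker_id, 2))
})

test_that("heavily corrupted reads fail the 80 percent similarity rule", {
  panel <- tiny_panel()
  target <- converted_targets(panel)[1]
  withr::with_seed(12, {
    ch <- strsplit(chartr("Y", "T", target), "")[[1]]
    hit <- sample(length(ch), round(0.3 * length(ch)))
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    bad <- paste(ch, collapse = "")
  })
  reads <- tibble::tibble(read_id = "bad", sequence = bad,
                          quality = strrep("F", nchar(bad)))
  calls <- process_reads(reads, panel)
  expect_equal(calls$status, "fail_similarity")
  expect_lt(calls$similarity, 0.8)
  # and the similarity equals the direct edit-distance computation
  d <- min(vapply(converted_targets(panel), function(t)
    cfbrain:::cpp_edit_distance(bad, t), numeric(1)))
  expect_equal(calls$similarity, unname(1 - d / nchar(target)))
})

test_that("reads shorter than half of every target are unassigned", {
  panel <- tiny_panel()
  stub <- substr(converted_targets(panel)[1], 1, 20)
  reads <- tibble::tibble(read_id = "short", sequence = chartr("Y", "T", stub),
                          quality = strrep("F", 20))
  calls <- process_reads(reads, panel)
  expect_equal(calls$status, "unassigned")
  expect_true(is.na(calls$marker_id))
})

test_that("CpG states are read off the CG/TG dinucleotide with ambiguity and coverage failures", {
  panel <- tiny_panel()
  one <- panel[1, ]
  pos <- one$cpg_pos[[1]]
  k <- length(pos)
  meth <- convert_det(one$sequence, pos, strrep("M", k))
  unmeth <- convert_det(one$sequence, pos, strrep("U", k))
  # CA at the first CpG site: ambiguous
  amb <- meth
  substr(amb, pos[1] + 1, pos[1] + 1) <- "A"
  # truncation before the last CpG: missing coverage
  trunc <- substr(unmeth, 1, pos[k])
  reads <- tibble::tibble(
    read_id = c("meth", "unmeth", "amb", "trunc"),
    sequence = c(meth, unmeth, amb, trunc),
    quality = strrep("F", nchar(c(meth, unmeth, amb, trunc))))
  calls <- process_reads(reads, panel)
  expect_equal(calls$status,
               c("pass", "pass", "fail_ambiguous_cpg", "fail_missing_cpg"))
  expect_equal(calls$pattern[1], strrep("C", k))
  expect_equal(calls$pattern[2], strrep("T", k))
  expect_equal(substr(calls$pattern[3], 1, 1), "?")
  lenient <- process_reads(reads, panel, ambiguous_policy = "lenient")
  expect_equal(lenient$status[3], "pass")
})

test_that("on error-free data every read passes and patterns equal the truth", {
  panel <- tiny_panel()
  reads <- simulate_reads(panel, 500, 0.3, conversion_rate = 1,
                          inappropriate_rate = 0, seq_error_rate = 0,
                          seed = 6)
  calls <- process_reads(reads, panel)
  expect_true(all(calls$status == "pass"))
  expect_identical(calls$marker_id, reads$marker_id)
  expect_identical(calls$pattern, chartr("MU", "CT", reads$pattern))
  report <- attr(calls, "report")
  expect_equal(sum(report), nrow(reads))
  expect_equal(unname(report["pass"]), nrow(reads), ignore_attr = TRUE)
})

test_that("every read lands in exactly one status category under noisy conditions", {
  panel <- tiny_panel()
  reads <- simulate_reads(panel, 2000, 0.1, conversion_rate = 0.95,
                          inappropriate_rate = 0.02, seq_error_rate = 0.01,
                          seed = 9)
  calls <- process_reads(reads, panel)
  expect_equal(nrow(calls), nrow(reads))
  expect_false(anyNA(calls$status))
  expect_equal(sum(attr(calls, "report")), nrow(reads))
})
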