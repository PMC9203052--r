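#' Demultiplex reads by sample barcode
#'
#' Assigns reads to samples by exact barcode match (0 mismatches by default;
#' up to 1 via `max_mismatch`). In `"header"` mode the barcode is the field
#' after the last colon of the read header; in `"prefix"` mode it is an
#' inline prefix of the read sequence, which is stripped (with its quality
#' characters) on assignment. Unassigned reads are retained with
#' `sample_id = NA` so that per-bin counts always sum to the input count.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param barcode_map Named character vector, `sample_id` -> barcode. All
#'   barcodes must be distinct and of equal length in prefix mode.
#' @param barcode_mode `"header"` or `"prefix"`.
#' @param max_mismatch Allowed barcode mismatches (0 or 1).
#' @return The reads tibble with a `sample_id` column (`NA` = unassigned);
#'   attribute `demux_counts` holds per-bin read counts.
#' @export
demultiplex <- function(reads, barcode_map,
                        barcode_mode = c("header", "prefix"),
                        max_mismatch = 0L) {
  barcode_mode <- match.arg(barcode_mode)
  if (anyDuplicated(barcode_map)) {
    abort("duplicate barcodes in barcode_map", class = "cfbrain_config_error")
  }
  if (max_mismatch < 0L || max_mismatch > 1L) {
    abort("max_mismatch must be 0 or 1", class = "cfbrain_config_error")
  }
  bc_len <- unique(nchar(barcode_map))
  if (barcode_mode == "prefix" && length(bc_len) != 1L) {
    abort("prefix mode needs equal-length barcodes", class = "cfbrain_config_error")
  }
  observed <- if (barcode_mode == "header") {
    sub(".*:", "", reads$read_id)
  } else {
    substr(reads$sequence, 1L, bc_len)
  }
  sample_of <- setNames(names(barcode_map), barcode_map)
  assigned <- unname(sample_of[observed])
  if (max_mismatch == 1L && anyNA(assigned)) {
    todo <- which(is.na(assigned) & nchar(observed) == bc_len[1])
    for (i in todo) {
      d <- hamming_chr(observed[i], barcode_map)
      hit <- which(d <= 1L)
      if (length(hit) == 1L) assigned[i] <- names(barcode_map)[hit]
    }
  }
  out <- reads
  out$sample_id <- assigned
  if (barcode_mode == "prefix") {
    keep <- !is.na(assigned)
    out$sequence[keep] <- substr(out$sequence[keep], bc_len + 1L,
                                 nchar(out$sequence[keep]))
    out$quality[keep] <- substr(out$quality[keep], bc_len + 1L,
                                nchar(out$quality[keep]))
  }
  counts <- table(factor(ifelse(is.na(assigned), "unassigned", assigned),
                         levels = c(names(barcode_map), "unassigned")))
  attr(out, "demux_counts") <- counts
  out
}

hamming_chr <- function(x, targets) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(targets, "", fixed = TRUE), function(t) {
    if (length(t) != length(xs)) return(Inf)
    sum(t != xs)
  }, numeric(1))
}

#' Mean-Phred quality filter
#'
#' A read passes when its mean Phred score is greater than or equal to
#' `min_mean_q` (boundary values pass). Empty reads fail.
#'
#' @param reads Tibble with `quality` (Phred+33 strings).
#' @param min_mean_q Threshold on the mean Phred score.
#' @return The tibble with `mean_q` and logical `pass_quality` columns.
#' @export
quality_filter <- function(reads, min_mean_q = 30) {
  mq <- cpp_mean_phred(reads$quality)
  reads$mean_q <- mq
  reads$pass_quality <- !is.na(mq) & mq >= min_mean_q
  reads
}

#' Assign reads to panel amplicons by edit-distance similarity
#'
#' Each read is compared against the in-silico fully bisulfite-converted
#' target of every amplicon, with CpG cytosines as the ambiguity code Y
#' (matching C or T) so methylation state cannot bias assignment.
#' Similarity is `1 - edit_distance / target_length`; the best marker is
#' kept, with ties broken by panel order (and flagged). Reads shorter than
#' half of every target are unassignable.
#'
#' @param reads Tibble with a `sequence` column.
#' @param panel Marker panel tibble.
#' @return The tibble with `marker_id`, `distance`, `similarity`, `tie` and
#'   `too_short` columns (`marker_id` is `NA` for unassignable reads).
#' @export
match_to_amplicon <- function(reads, panel) {
  if (nrow(panel) == 0L) {
    abort("panel is empty", class = "cfbrain_config_error")
  }
  tg <- converted_targets(panel)
  m <- cpp_match_reads(reads$sequence, unname(tg))
  reads$marker_id <- panel$marker_id[m$marker]
  reads$distance <- m$distance
  reads$similarity <- m$similarity
  reads$tie <- m$tie
  reads$too_short <- m$too_short
  reads
}

#' Call per-CpG methylation states for assigned reads
#'
#' At each expected CpG of the assigned amplicon (positions mapped through
#' the read-target alignment) the read dinucleotide is interpreted as:
#' CG = methylated (`C`), TG = unmethylated (`T`), anything else ambiguous
#' (`?`); a CpG aligned to a gap or not covered by the read is missing (`.`).
#'
#' @param reads Tibble from [match_to_amplicon()].
#' @param panel Marker panel tibble.
#' @return The tibble with `pattern`, `n_missing` and `n_ambiguous` columns.
#' @export
call_cpgs <- function(reads, panel) {
  tg <- converted_targets(panel)
  idx <- match(reads$marker_id, panel$marker_id)
  res <- cpp_call_patterns(reads$sequence, idx, reads$distance, unname(tg),
                           lapply(panel$cpg_pos, as.integer))
  reads$pattern <- as.character(res$pattern)
  reads$n_missing <- res$n_missing
  reads$n_ambiguous <- res$n_ambiguous
  reads
}

#' Run the per-read processing pipeline: filter, match, call
#'
#' Applies the mean-quality filter, assigns passing reads to amplicons,
#' calls CpG states, and classifies every read into exactly one status:
#' `pass`, `fail_quality`, `unassigned`, `fail_similarity`,
#' `fail_missing_cpg` or `fail_ambiguous_cpg`. Under the default strict
#' policy any ambiguous CpG invalidates the molecule; the lenient policy
#' keeps such molecules as `pass` with `?` states (they are treated as
#' uncalled downstream).
#'
#' @param reads Tibble with `read_id`, `sample_id`, `sequence`, `quality`.
#' @param panel Marker panel tibble.
#' @param min_mean_q Mean-Phred threshold.
#' @param min_similarity Similarity threshold for amplicon assignment.
#' @param ambiguous_policy `"strict"` or `"lenient"`.
#' @return Tibble of molecule calls: `read_id`, `sample_id`, `marker_id`,
#'   `similarity`, `pattern`, `status`; attribute `report` carries per-status
#'   counts that sum to the input read count.
#' @export
process_reads <- function(reads, panel, min_mean_q = 30,
                          min_similarity = 0.8,
                          ambiguous_policy = c("strict", "lenient")) {
  ambiguous_policy <- match.arg(ambiguous_policy)
  stopifnot(is.data.frame(reads))
  if (!"sample_id" %in% names(reads)) {
    reads$sample_id <- rep("sample1", nrow(reads))
  }
  if (nrow(reads) == 0L) {
    out <- tibble(read_id = character(), sample_id = character(),
                  marker_id = character(), similarity = numeric(),
                  pattern = character(), status = character())
    attr(out, "report") <- table(factor(character(),
      levels = c("pass", "fail_quality", "fail_similarity",
                 "fail_missing_cpg", "fail_ambiguous_cpg", "unassigned")))
    return(out)
  }
  reads <- quality_filter(reads, min_mean_q)
  ok <- reads$pass_quality & !is.na(reads$sample_id)
  passq <- reads[ok, , drop = FALSE]
  failq <- reads[!ok, , drop = FALSE]
  out_fail <- NULL
  if (nrow(failq)) {
    out_fail <- tibble(read_id = failq$read_id, sample_id = failq$sample_id,
                       marker_id = NA_character_, similarity = NA_real_,
                       pattern = NA_character_,
                       status = ifelse(is.na(failq$sample_id), "unassigned",
                                       "fail_quality"))
  }
  out_pass <- NULL
  if (nrow(passq)) {
    passq <- match_to_amplicon(passq, panel)
    passq <- call_cpgs(passq, panel)
    status <- dplyr::case_when(
      passq$too_short ~ "unassigned",
      passq$similarity < min_similarity ~ "fail_similarity",
      passq$n_missing > 0L ~ "fail_missing_cpg",
      ambiguous_policy == "strict" & passq$n_ambiguous > 0L ~ "fail_ambiguous_cpg",
      TRUE ~ "pass"
    )
    out_pass <- tibble(read_id = passq$read_id, sample_id = passq$sample_id,
                       marker_id = ifelse(status %in% c("pass",
                                                        "fail_missing_cpg",
                                                        "fail_ambiguous_cpg"),
                                          passq$marker_id, passq$marker_id),
                       similarity = passq$similarity,
                       pattern = passq$pattern, status = status)
    out_pass$marker_id[status == "unassigned"] <- NA_character_
    out_pass$pattern[status %in% c("unassigned", "fail_similarity")] <- NA_character_
  }
  out <- bind_rows(out_fail, out_pass)
  out <- out[match(reads$read_id, out$read_id), , drop = FALSE]
  lv <- c("pass", "fail_quality", "fail_similarity", "fail_missing_cpg",
          "fail_ambiguous_cpg", "unassigned")
  report <- table(factor(out$status, levels = lv))
  stopifnot(sum(report) == nrow(reads))
  attr(out, "report") <- report
  out
}
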