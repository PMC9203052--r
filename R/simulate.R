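#' Simulate per-molecule methylation patterns from a two-population mixture
#'
#' Each molecule of a marker is drawn from the target tissue (brain) with
#' probability `target_fraction`, in which case all of its CpGs are
#' unmethylated, and otherwise from the fully methylated background
#' (leukocyte-like). An optional per-CpG noise flip rate perturbs patterns to
#' probe robustness; it is 0 by default.
#'
#' @param panel Marker panel tibble.
#' @param n_molecules_per_marker Molecules simulated per marker (sequencing
#'   depth before filtering).
#' @param target_fraction Single fraction in \[0, 1\], or a named vector with
#'   one fraction per `marker_id`.
#' @param noise_flip_rate Per-CpG probability of flipping a pattern state.
#' @param seed Optional integer seed.
#' @return Tibble with `molecule_id`, `marker_id`, `origin`
#'   (`target_tissue`/`background`) and `pattern` (string over `M`/`U`, one
#'   character per CpG).
#' @export
simulate_molecules <- function(panel, n_molecules_per_marker,
                               target_fraction, noise_flip_rate = 0,
                               seed = NULL) {
  n <- assert_count(n_molecules_per_marker, "n_molecules_per_marker")
  assert_rate(noise_flip_rate, "noise_flip_rate")
  fr <- marker_fractions(panel, target_fraction)
  with_seed_if(seed, {
    rows <- purrr::pmap(list(panel$marker_id, panel$cpg_pos), function(id, pos) {
      k <- length(pos)
      f <- fr[[id]]
      from_target <- runif(n) < f
      pattern <- ifelse(from_target, strrep("U", k), strrep("M", k))
      if (noise_flip_rate > 0) pattern <- flip_states(pattern, k, noise_flip_rate)
      tibble(molecule_id = sprintf("%s_m%06d", id, seq_len(n)),
             marker_id = id,
             origin = ifelse(from_target, "target_tissue", "background"),
             pattern = pattern)
    })
    bind_rows(rows)
  })
}

marker_fractions <- function(panel, target_fraction) {
  if (length(target_fraction) == 1L && is.null(names(target_fraction))) {
    assert_rate(target_fraction, "target_fraction")
    return(setNames(rep(target_fraction, nrow(panel)), panel$marker_id))
  }
  if (!all(panel$marker_id %in% names(target_fraction))) {
    abort("named `target_fraction` must cover every marker_id",
          class = "cfbrain_config_error")
  }
  if (any(target_fraction < 0 | target_fraction > 1)) {
    abort("`target_fraction` values must lie in [0, 1]",
          class = "cfbrain_config_error")
  }
  as.list(target_fraction[panel$marker_id])
}

flip_states <- function(pattern, k, rate) {
  m <- matrix(unlist(strsplit(pattern, "", fixed = TRUE)), ncol = k,
              byrow = TRUE)
  flip <- matrix(runif(length(m)) < rate, ncol = k)
  m[flip] <- ifelse(m[flip] == "U", "M", "U")
  apply(m, 1L, paste, collapse = "")
}

#' Apply in-silico bisulfite conversion to molecule patterns
#'
#' Emulates bisulfite chemistry on the top strand of an amplicon template:
#' unmethylated cytosines (all non-CpG cytosines, plus CpG cytosines whose
#' state is `U`) read as T with probability `conversion_rate`; methylated CpG
#' cytosines read as T with probability `inappropriate_rate`. A, G and T are
#' untouched and read length is preserved.
#'
#' @param sequence Unconverted template sequence (A/C/G/T).
#' @param cpg_pos Integer vector of 1-based CpG cytosine positions.
#' @param pattern Character vector of methylation patterns (strings over
#'   `M`/`U`, one character per CpG); one output sequence per pattern.
#' @param conversion_rate Probability an unmethylated C converts to T.
#' @param inappropriate_rate Probability a methylated C converts to T.
#' @param seed Optional integer seed.
#' @return Character vector of converted sequences, one per pattern.
#' @export
bisulfite_convert <- function(sequence, cpg_pos, pattern,
                              conversion_rate = 1, inappropriate_rate = 0,
                              seed = NULL) {
  assert_rate(conversion_rate, "conversion_rate")
  assert_rate(inappropriate_rate, "inappropriate_rate")
  cpg_pos <- as.integer(cpg_pos)
  if (any(substring(sequence, cpg_pos, cpg_pos + 1L) != "CG")) {
    abort("cpg_pos does not point at CG dinucleotides in `sequence`",
          class = "cfbrain_structure_error")
  }
  if (any(nchar(pattern) != length(cpg_pos))) {
    abort("pattern length must equal the number of CpGs",
          class = "cfbrain_structure_error")
  }
  with_seed_if(seed,
    as.character(cpp_convert_molecules(sequence, cpg_pos, pattern,
                                       conversion_rate, inappropriate_rate)))
}

#' Simulate sequenced amplicon reads for one sample
#'
#' Draws molecules with [simulate_molecules()], converts them with the
#' bisulfite model, applies substitution sequencing errors, and attaches
#' constant-quality Phred strings (Q37 by default). The returned tibble
#' carries the ground truth (`marker_id`, `origin`, `pattern`) next to each
#' read, serving as the oracle for downstream tests.
#'
#' @inheritParams simulate_molecules
#' @param conversion_rate,inappropriate_rate Bisulfite model rates.
#' @param seq_error_rate Per-base substitution error rate.
#' @param quality_char Single Phred+33 character used for all bases.
#' @param sample_id Sample label attached to every read.
#' @return Tibble with `read_id`, `sample_id`, `sequence`, `quality`, and
#'   truth columns `marker_id`, `origin`, `pattern`.
#' @export
simulate_reads <- function(panel, n_molecules_per_marker, target_fraction,
                           conversion_rate = 0.99, inappropriate_rate = 0.005,
                           seq_error_rate = 0.001, noise_flip_rate = 0,
                           quality_char = "F", sample_id = "sample1",
                           seed = NULL) {
  assert_rate(seq_error_rate, "seq_error_rate")
  with_seed_if(seed, {
    mol <- simulate_molecules(panel, n_molecules_per_marker, target_fraction,
                              noise_flip_rate = noise_flip_rate, seed = NULL)
    by_marker <- split(mol, factor(mol$marker_id, levels = panel$marker_id))
    seqs <- purrr::pmap(list(panel$sequence, panel$cpg_pos, panel$marker_id),
                        function(s, pos, id) {
      conv <- cpp_convert_molecules(s, as.integer(pos),
                                    by_marker[[id]]$pattern,
                                    conversion_rate, inappropriate_rate)
      if (seq_error_rate > 0) conv <- cpp_add_seq_errors(conv, seq_error_rate)
      as.character(conv)
    })
    mol <- bind_rows(by_marker)
    mol$sequence <- unlist(seqs)
    mol$quality <- strrep(quality_char, nchar(mol$sequence))
    mol |>
      mutate(read_id = .data$molecule_id, sample_id = sample_id) |>
      select("read_id", "sample_id", "sequence", "quality",
             "marker_id", "origin", "pattern")
  })
}

#' Write simulated reads as FASTQ plus a truth table
#'
#' Emits one 4-line Phred+33 FASTQ record per read. The sample barcode is
#' encoded either in the read header as the field after the last colon
#' (TruSeq-index style, the default) or as an inline prefix of the read
#' sequence. A truth TSV (read_id, marker_id, origin, pattern) is written
#' alongside unless `truth_path` is `NULL`.
#'
#' @param reads Tibble from [simulate_reads()] (columns `read_id`,
#'   `sample_id`, `sequence`, `quality`; truth columns optional).
#' @param fastq_path Output FASTQ path.
#' @param barcode_map Named character vector, `sample_id` -> barcode.
#' @param barcode_mode `"header"` or `"prefix"`.
#' @param truth_path Output truth TSV path, or `NULL` to skip.
#' @return `fastq_path`, invisibly.
#' @export
emit_fastq <- function(reads, fastq_path,
                       barcode_map = c(sample1 = "ACGTACGT"),
                       barcode_mode = c("header", "prefix"),
                       truth_path = paste0(fastq_path, ".truth.tsv")) {
  barcode_mode <- match.arg(barcode_mode)
  if (anyDuplicated(barcode_map)) {
    abort("barcodes must be unique", class = "cfbrain_config_error")
  }
  missing <- setdiff(unique(reads$sample_id), names(barcode_map))
  if (length(missing)) {
    abort(paste("no barcode for sample(s):", paste(missing, collapse = ", ")),
          class = "cfbrain_config_error")
  }
  bc <- unname(barcode_map[reads$sample_id])
  if (nrow(reads) == 0L) {
    writeLines(character(0), fastq_path)
  } else if (barcode_mode == "header") {
    ids <- paste0(reads$read_id, ":", bc)
    write_fastq(ids, reads$sequence, reads$quality, fastq_path)
  } else {
    write_fastq(reads$read_id, paste0(bc, reads$sequence),
                paste0(strrep("I", nchar(bc)), reads$quality), fastq_path)
  }
  if (!is.null(truth_path)) {
    truth_cols <- intersect(c("read_id", "sample_id", "marker_id", "origin",
                              "pattern"), names(reads))
    readr::write_tsv(reads[truth_cols], truth_path, na = ".")
  }
  invisible(fastq_path)
}

write_fastq <- function(ids, seqs, quals, path) {
  # QualityScaledDNAStringSet warns about dropping (empty) metadata columns
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals)))
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (4-line records, Phred+33).
#' @return Tibble with `read_id` (full header), `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(paste("FASTQ not found:", path), class = "cfbrain_io_error")
  }
  if (file.size(path) == 0L) {
    return(tibble(read_id = character(), sequence = character(),
                  quality = character()))
  }
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(read_id = names(x),
         sequence = unname(as.character(x)),
         quality = unname(as.character(Biostrings::quality(x))))
}
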