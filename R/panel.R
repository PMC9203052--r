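#' Generate a synthetic amplicon marker panel
#'
#' Creates a panel of bisulfite-PCR amplicon targets with planted CpG sites,
#' grouped into brain cell-type classes. The default geometry mirrors a
#' 13-marker brain panel: four neuron, three astrocyte, three oligodendrocyte
#' and three whole-brain amplicons. Sequences are random DNA in which CpG
#' dinucleotides occur only at the planted positions, and every amplicon
#' contains at least one non-CpG cytosine so that bisulfite conversion can be
#' monitored independently of methylation state.
#'
#' @param n_per_cell_type Named integer vector, amplicons per cell-type class.
#'   Names become the `cell_type` column.
#' @param n_cpgs_range Integer pair, inclusive range of CpG count per amplicon.
#' @param amplicon_length Amplicon length in bp (>= 40). 100 bp by default,
#'   compatible with the ~170 bp fragments of plasma cfDNA.
#' @param seed Integer seed; identical seeds give identical panels.
#' @return A tibble of class `cfb_panel` with columns `marker_id`,
#'   `cell_type`, `chrom`, `start`, `end` (0-based half-open synthetic
#'   coordinates), `length`, `sequence` and `cpg_pos` (list column of 1-based
#'   positions of the C of each CpG).
#' @export
generate_marker_panel <- function(n_per_cell_type = c(neuron = 4,
                                                      astrocyte = 3,
                                                      oligodendrocyte = 3,
                                                      whole_brain = 3),
                                  n_cpgs_range = c(3L, 6L),
                                  amplicon_length = 100L,
                                  seed = 1L) {
  if (is.null(names(n_per_cell_type)) || any(!nzchar(names(n_per_cell_type)))) {
    abort("`n_per_cell_type` must be a named vector", class = "cfbrain_config_error")
  }
  if (any(n_per_cell_type < 0) || any(n_per_cell_type != as.integer(n_per_cell_type))) {
    abort("`n_per_cell_type` entries must be non-negative integers",
          class = "cfbrain_config_error")
  }
  amplicon_length <- assert_count(amplicon_length, "amplicon_length", min = 40L)
  n_cpgs_range <- as.integer(n_cpgs_range)
  if (length(n_cpgs_range) != 2L || n_cpgs_range[1] < 1L ||
      n_cpgs_range[1] > n_cpgs_range[2]) {
    abort("`n_cpgs_range` must be an increasing positive integer pair",
          class = "cfbrain_config_error")
  }
  # CpG cytosines need positions in 1..(L-1) separated by >= 2, and room must
  # remain for at least one non-CpG cytosine.
  if (2L * n_cpgs_range[2] + 2L > amplicon_length) {
    abort(sprintf("cannot place up to %d CpGs in a %d bp amplicon",
                  n_cpgs_range[2], amplicon_length),
          class = "cfbrain_config_error")
  }

  cell_types <- rep(names(n_per_cell_type), times = n_per_cell_type)
  n_amp <- length(cell_types)
  if (n_amp == 0L) {
    return(new_panel(tibble(
      marker_id = character(), cell_type = character(), chrom = character(),
      start = integer(), end = integer(), length = integer(),
      sequence = character(), cpg_pos = list()
    )))
  }

  with_seed_if(seed, {
    rows <- purrr::imap(cell_types, function(ct, i) {
      k <- if (n_cpgs_range[1] == n_cpgs_range[2]) n_cpgs_range[1] else
        sample(seq(n_cpgs_range[1], n_cpgs_range[2]), 1L)
      seq_chr <- random_amplicon(amplicon_length, k)
      tibble(
        marker_id = sprintf("%s_%02d", ct, sum(cell_types[seq_len(i)] == ct)),
        cell_type = ct,
        chrom = "chrS",
        start = (i - 1L) * 10000L,
        end = (i - 1L) * 10000L + amplicon_length,
        length = amplicon_length,
        sequence = seq_chr$sequence,
        cpg_pos = list(seq_chr$cpg_pos)
      )
    })
    new_panel(bind_rows(rows))
  })
}

# One random amplicon with exactly k planted CpGs, no accidental CpG, and at
# least one non-CpG cytosine.
random_amplicon <- function(len, k) {
  repeat {
    pos <- sort(sample(seq_len(len - 1L), k))
    if (k == 1L || all(diff(pos) >= 2L)) break
  }
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
              prob = c(0.3, 0.2, 0.2, 0.3))
  s[pos] <- "C"
  s[pos + 1L] <- "G"
  repeat {
    cg <- which(s[-len] == "C" & s[-1] == "G")
    stray <- setdiff(cg, pos)
    if (!length(stray)) break
    s[stray + 1L] <- "A"
  }
  non_cpg_c <- setdiff(which(s == "C"), pos)
  if (!length(non_cpg_c)) {
    ok <- setdiff(seq_len(len), c(pos, pos + 1L))
    ok <- ok[!(ok < len & s[pmin(ok + 1L, len)] == "G")]
    ok <- ok[!(ok > 1L & s[pmax(ok - 1L, 1L)] == "C" & FALSE)]  # C before is harmless
    s[ok[1L]] <- "C"
  }
  list(sequence = paste(s, collapse = ""), cpg_pos = as.integer(pos))
}

new_panel <- function(x) {
  class(x) <- c("cfb_panel", class(x))
  x
}

#' Validate marker panel invariants
#'
#' Checks that every recorded CpG position carries a CG dinucleotide, that
#' positions are strictly increasing with at least one CpG per amplicon, and
#' that lengths are consistent.
#'
#' @param panel A panel tibble as from [generate_marker_panel()].
#' @return The panel, invisibly; aborts on violation.
#' @export
validate_panel <- function(panel) {
  req <- c("marker_id", "cell_type", "sequence", "cpg_pos")
  if (!all(req %in% names(panel))) {
    abort(paste("panel is missing columns:",
                paste(setdiff(req, names(panel)), collapse = ", ")),
          class = "cfbrain_structure_error")
  }
  if (anyDuplicated(panel$marker_id)) {
    abort("duplicated marker_id in panel", class = "cfbrain_structure_error")
  }
  purrr::pwalk(list(panel$marker_id, panel$sequence, panel$cpg_pos),
               function(id, s, pos) {
    pos <- as.integer(pos)
    if (!length(pos)) {
      abort(sprintf("marker %s has no CpG", id), class = "cfbrain_structure_error")
    }
    if (is.unsorted(pos, strictly = TRUE)) {
      abort(sprintf("marker %s: CpG positions not strictly increasing", id),
            class = "cfbrain_structure_error")
    }
    dinuc <- substring(s, pos, pos + 1L)
    if (any(dinuc != "CG")) {
      abort(sprintf("marker %s: CpG position without CG dinucleotide", id),
            class = "cfbrain_structure_error")
    }
  })
  if ("length" %in% names(panel) &&
      any(panel$length != nchar(panel$sequence))) {
    abort("panel length column disagrees with sequence length",
          class = "cfbrain_structure_error")
  }
  invisible(panel)
}

#' In-silico fully bisulfite-converted target sequences
#'
#' Converts every non-CpG cytosine to T and replaces each CpG cytosine with
#' the IUPAC ambiguity code Y (C or T), so that read-to-target similarity is
#' independent of methylation state.
#'
#' @param panel A panel tibble.
#' @return Character vector of converted targets, named by `marker_id`.
#' @export
converted_targets <- function(panel) {
  out <- purrr::map2_chr(panel$sequence, panel$cpg_pos, function(s, pos) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    ch[ch == "C"] <- "T"
    ch[as.integer(pos)] <- "Y"
    paste(ch, collapse = "")
  })
  setNames(out, panel$marker_id)
}

#' Write / read a marker panel on disk
#'
#' The on-disk representation is a BED-like TSV (`<prefix>.bed`: chrom,
#' start, end, marker_id, cell_type; 0-based half-open), a FASTA of target
#' sequences (`<prefix>.fa`) and a TSV of 0-based CpG offsets
#' (`<prefix>_cpgs.tsv`: marker_id, comma-separated offsets).
#'
#' @param panel A panel tibble.
#' @param prefix Path prefix for the three files.
#' @return `write_marker_panel()` returns the prefix invisibly;
#'   `read_marker_panel()` returns the panel tibble.
#' @export
write_marker_panel <- function(panel, prefix) {
  validate_panel(panel)
  bed <- tibble(chrom = panel$chrom %||% "chrS",
                start = panel$start %||% 0L,
                end = panel$end %||% nchar(panel$sequence),
                marker_id = panel$marker_id,
                cell_type = panel$cell_type)
  readr::write_tsv(bed, paste0(prefix, ".bed"), col_names = FALSE)
  seqs <- Biostrings::DNAStringSet(setNames(panel$sequence, panel$marker_id))
  Biostrings::writeXStringSet(seqs, paste0(prefix, ".fa"))
  cpgs <- tibble(marker_id = panel$marker_id,
                 cpg_offsets = purrr::map_chr(panel$cpg_pos, function(p)
                   paste(as.integer(p) - 1L, collapse = ",")))
  readr::write_tsv(cpgs, paste0(prefix, "_cpgs.tsv"))
  invisible(prefix)
}

#' @rdname write_marker_panel
#' @export
read_marker_panel <- function(prefix) {
  bed <- readr::read_tsv(paste0(prefix, ".bed"),
                         col_names = c("chrom", "start", "end", "marker_id",
                                       "cell_type"),
                         col_types = "ciicc", progress = FALSE)
  seqs <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  cpgs <- readr::read_tsv(paste0(prefix, "_cpgs.tsv"), col_types = "cc",
                          progress = FALSE)
  panel <- bed |>
    mutate(sequence = as.character(seqs[.data$marker_id]),
           length = nchar(.data$sequence)) |>
    left_join(cpgs, by = "marker_id") |>
    mutate(cpg_pos = purrr::map(.data$cpg_offsets, function(x)
      as.integer(strsplit(x, ",", fixed = TRUE)[[1]]) + 1L)) |>
    select(-"cpg_offsets")
  validate_panel(new_panel(as_tibble(panel)))
}
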