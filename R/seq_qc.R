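#' Quality-control configuration for COI amplicons
#'
#' Bundles the tunable parameters of the amplicon QC stage. Primer sequences
#' have no default: when left empty, primer trimming is skipped. Length
#' thresholds separate the hard NUMT-size filter (sequences shorter than
#' `min_length_nt` are treated as putative nuclear pseudogene fragments,
#' vertebrate NUMTs being typically under 600 bp) from the soft expected
#' window (full-length COI amplicons of this assay run 636-655 nt; lengths
#' outside the window but inside the hard bounds pass with a warning).
#'
#' @param primer_forward,primer_reverse Primer sequences (5'->3') as
#'   character strings; `""` disables trimming at that end.
#' @param max_primer_mismatch Maximum mismatches tolerated when locating a
#'   primer (default 1).
#' @param genetic_code_id NCBI translation table identifier; default `2`,
#'   the vertebrate mitochondrial code (AGA/AGG stop, TGA Trp, ATA Met).
#' @param min_length_nt,max_length_nt Hard length bounds in nucleotides
#'   (defaults 600 and 700).
#' @param expected_window Length-2 integer vector, the soft expected length
#'   window (default `c(636, 655)`).
#' @param max_n_fraction Maximum tolerated fraction of ambiguous (N) bases
#'   (default 0.01). Codons containing N translate to `X` and never count
#'   as stops.
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(primer_forward = "", primer_reverse = "",
                      max_primer_mismatch = 1L, genetic_code_id = 2L,
                      min_length_nt = 600L, max_length_nt = 700L,
                      expected_window = c(636L, 655L),
                      max_n_fraction = 0.01) {
  stopifnot(min_length_nt < max_length_nt, length(expected_window) == 2,
            expected_window[1] <= expected_window[2],
            max_n_fraction >= 0, max_n_fraction <= 1)
  if (expected_window[1] < min_length_nt || expected_window[2] > max_length_nt) {
    warning("expected_window is not nested within [min_length_nt, max_length_nt]")
  }
  structure(list(primer_forward = toupper(primer_forward),
                 primer_reverse = toupper(primer_reverse),
                 max_primer_mismatch = as.integer(max_primer_mismatch),
                 genetic_code_id = as.integer(genetic_code_id),
                 min_length_nt = as.integer(min_length_nt),
                 max_length_nt = as.integer(max_length_nt),
                 expected_window = as.integer(expected_window),
                 max_n_fraction = max_n_fraction),
            class = "qc_config")
}

#' Read COI amplicon sequences from a FASTA file
#'
#' Record headers follow the `sampleCode|replicateIndex` convention (e.g.
#' `>MIL1T|2`); a header without `|` yields `NA` replicate and the whole
#' header as sample code. Sequences are upper-cased and U is converted to T.
#'
#' @param path Path to a FASTA file (wrapped or single-line).
#' @return A tibble with columns `read_id`, `sample_code`, `replicate_index`
#'   and `sequence`, one row per record in file order.
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA (", path, "): ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0) {
    return(tibble::tibble(read_id = character(), sample_code = character(),
                          replicate_index = integer(), sequence = character()))
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- check_alphabet(as.character(set), ids)
  parts <- stringr::str_split_fixed(ids, stringr::fixed("|"), 2)
  rep_idx <- suppressWarnings(as.integer(parts[, 2]))
  tibble::tibble(
    read_id = ids,
    sample_code = ifelse(parts[, 1] == "", ids, parts[, 1]),
    replicate_index = rep_idx,
    sequence = unname(seqs)
  )
}

# Leftmost occurrence (1-based start) of `pattern` in `x` with at most
# `max_mismatch` mismatched positions, or NA. N in either string matches
# anything. Plain sliding-window scan: primers are short.
find_approx <- function(pattern, x, max_mismatch, from_end = FALSE) {
  pl <- nchar(pattern); xl <- nchar(x)
  if (pl == 0 || pl > xl) return(NA_integer_)
  pv <- strsplit(pattern, "")[[1]]
  xv <- strsplit(x, "")[[1]]
  starts <- seq_len(xl - pl + 1)
  if (from_end) starts <- rev(starts)
  for (s in starts) {
    w <- xv[s:(s + pl - 1)]
    mm <- sum(w != pv & w != "N" & pv != "N")
    if (mm <= max_mismatch) return(s)
  }
  NA_integer_
}

rev_comp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Trim PCR primers from an amplicon sequence
#'
#' Locates the forward primer near the 5' end and removes it together with
#' everything upstream; analogously removes the reverse complement of the
#' reverse primer and everything downstream at the 3' end. If the forward
#' primer is only found on the reverse complement of the read, the read is
#' re-oriented first. Unset (empty) primers disable the corresponding trim;
#' a read with no primer occurrence is returned unchanged with a message.
#'
#' @param sequence A nucleotide string (ACGTN).
#' @param config A [qc_config()]; `primer_forward`/`primer_reverse` and
#'   `max_primer_mismatch` are used.
#' @param quiet Suppress the no-occurrence message.
#' @return The trimmed sequence (possibly re-oriented).
#' @export
trim_primers <- function(sequence, config = qc_config(), quiet = FALSE) {
  sequence <- check_alphabet(sequence)
  fwd <- config$primer_forward
  rev <- config$primer_reverse
  k <- config$max_primer_mismatch
  if (!nzchar(fwd) && !nzchar(rev)) return(sequence)
  trimmed <- FALSE
  if (nzchar(fwd)) {
    pos <- find_approx(fwd, sequence, k)
    if (is.na(pos)) {
      rc <- rev_comp(sequence)
      pos_rc <- find_approx(fwd, rc, k)
      if (!is.na(pos_rc)) {
        sequence <- rc
        pos <- pos_rc
      }
    }
    if (!is.na(pos)) {
      sequence <- substr(sequence, pos + nchar(fwd), nchar(sequence))
      trimmed <- TRUE
    }
  }
  if (nzchar(rev)) {
    rc_rev <- rev_comp(rev)
    pos <- find_approx(rc_rev, sequence, k, from_end = TRUE)
    if (!is.na(pos)) {
      sequence <- substr(sequence, 1, pos - 1)
      trimmed <- TRUE
    }
  }
  if (!trimmed && !quiet) message("no primer occurrence found; sequence unchanged")
  if (nchar(sequence) < 50) {
    stop("primer trimming left fewer than 50 nt", call. = FALSE)
  }
  sequence
}

#' Translate a nucleotide sequence in a given frame and strand
#'
#' Translates under an NCBI genetic-code table (default 2, the vertebrate
#' mitochondrial code). `frame_offset` leading bases are skipped after
#' optional reverse complementation; the incomplete trailing codon is
#' dropped. Stop codons are rendered as `*`; codons containing N that do
#' not resolve unambiguously are rendered as `X`.
#'
#' @param sequence Nucleotide string (ACGTN).
#' @param frame_offset 0, 1 or 2 skipped leading bases.
#' @param strand `"forward"` or `"reverse"`.
#' @param genetic_code_id NCBI translation table id (default 2).
#' @return Amino-acid string of length `floor((nchar - frame_offset)/3)`.
#' @export
#' @examples
#' translate_dna("ATGGCC")          # "MA"
#' translate_dna("AGA")             # "*" under the vertebrate mito code
#' translate_dna("AGA", genetic_code_id = 1)  # "R" under the standard code
translate_dna <- function(sequence, frame_offset = 0L,
                          strand = c("forward", "reverse"),
                          genetic_code_id = 2L) {
  strand <- match.arg(strand)
  stopifnot(frame_offset %in% 0:2)
  sequence <- check_alphabet(sequence)
  code <- lookup_genetic_code(genetic_code_id)
  if (strand == "reverse") sequence <- rev_comp(sequence)
  s <- substr(sequence, frame_offset + 1, nchar(sequence))
  n_codon <- nchar(s) %/% 3
  if (n_codon == 0) return("")
  s <- substr(s, 1, n_codon * 3)
  as.character(Biostrings::translate(Biostrings::DNAStringSet(s),
                                     genetic.code = code,
                                     if.fuzzy.codon = "solve",
                                     no.init.codon = TRUE))
}

lookup_genetic_code <- function(genetic_code_id) {
  id <- as.character(genetic_code_id)
  supported <- Biostrings::GENETIC_CODE_TABLE$id
  if (!id %in% supported) {
    stop("unknown genetic_code_id '", id, "'; supported NCBI tables: ",
         paste(supported, collapse = ", "), call. = FALSE)
  }
  Biostrings::getGeneticCode(id)
}

# Internal stop count of an amino-acid string: '*' anywhere before the
# final residue (a terminal stop is not counted as internal).
internal_stops <- function(aa) {
  if (nchar(aa) <= 1) return(0L)
  body <- substr(aa, 1, nchar(aa) - 1)
  stringr::str_count(body, stringr::fixed("*"))
}

# Six frame/strand translations, returned as a tibble ordered by the
# deterministic tie-break preference: forward before reverse, frame 0,1,2.
six_frame_stops <- function(sequence, genetic_code_id = 2L) {
  grid <- tidyr::expand_grid(strand = c("forward", "reverse"),
                             frame_offset = 0:2)
  grid$stops <- as.integer(six_frame_stop_matrix(sequence, genetic_code_id))
  grid
}

# Internal-stop counts for a whole vector of sequences at once: one
# n x 6 matrix, columns in tie-break order (forward 0,1,2 then reverse
# 0,1,2). Batches the Biostrings translation, which matters when QC runs
# over thousands of reads.
six_frame_stop_matrix <- function(sequences, genetic_code_id = 2L) {
  code <- lookup_genetic_code(genetic_code_id)
  n <- length(sequences)
  out <- matrix(0L, nrow = n, ncol = 6)
  fwd <- Biostrings::DNAStringSet(sequences)
  sets <- list(fwd, Biostrings::reverseComplement(fwd))
  lens <- nchar(sequences)
  col <- 0L
  for (set in sets) {
    for (f in 0:2) {
      col <- col + 1L
      width <- pmax(((lens - f) %/% 3) * 3, 0L)
      keep <- width > 0
      if (!any(keep)) next
      sub <- Biostrings::subseq(set[keep], start = f + 1L, width = width[keep])
      aa <- as.character(Biostrings::translate(sub, genetic.code = code,
                                               if.fuzzy.codon = "solve",
                                               no.init.codon = TRUE))
      body <- substr(aa, 1, pmax(nchar(aa) - 1, 0))
      out[keep, col] <- stringr::str_count(body, stringr::fixed("*"))
    }
  }
  out
}

#' Screen a primer-trimmed amplicon for NUMT signatures
#'
#' Translates the sequence in all six frame/strand combinations under the
#' configured genetic code and picks the combination with the fewest
#' internal stop codons (ties broken deterministically: forward strand
#' first, then lowest frame offset). A sequence is flagged as a putative
#' NUMT when even the best combination retains an internal stop, or when it
#' is shorter than the hard minimum length. Over-long and N-rich sequences
#' fail QC without the NUMT flag. Lengths inside the hard bounds but
#' outside the expected window pass with a warning.
#'
#' @param sequence Nucleotide string, already primer-trimmed.
#' @param config A [qc_config()].
#' @param read_id Optional identifier carried into the result.
#' @return A one-row tibble: `read_id`, `trimmed_sequence`, `strand`,
#'   `frame_offset`, `internal_stop_count`, `length_nt`, `numt_flag`,
#'   `fail_reason` (`NA` when the read passes).
#' @export
screen_numt <- function(sequence, config = qc_config(), read_id = NA_character_) {
  screen_numt_batch(sequence, config, read_id)
}

# Vectorized core of screen_numt: one row per input sequence.
screen_numt_batch <- function(sequences, config = qc_config(),
                              read_ids = NA_character_) {
  sequences <- check_alphabet(sequences, read_ids)
  read_ids <- rep_len(read_ids, length(sequences))
  len <- nchar(sequences)
  n_frac <- stringr::str_count(sequences, stringr::fixed("N")) / len
  stops <- six_frame_stop_matrix(sequences, config$genetic_code_id)
  best_idx <- max.col(-stops, ties.method = "first")
  best_strand <- c("forward", "forward", "forward",
                   "reverse", "reverse", "reverse")[best_idx]
  best_frame <- c(0L, 1L, 2L, 0L, 1L, 2L)[best_idx]
  best_stops <- stops[cbind(seq_along(sequences), best_idx)]

  fail <- dplyr::case_when(
    n_frac > config$max_n_fraction ~ "ambiguous_bases",
    len > config$max_length_nt ~ "too_long",
    best_stops > 0 ~ "stops_in_all_frames",
    len < config$min_length_nt ~ "too_short",
    TRUE ~ NA_character_
  )
  odd_len <- is.na(fail) & (len < config$expected_window[1] |
                              len > config$expected_window[2])
  if (any(odd_len)) {
    warning(sum(odd_len), " read(s) with length outside the expected window [",
            config$expected_window[1], ", ", config$expected_window[2],
            "] passed QC", call. = FALSE)
  }
  tibble::tibble(
    read_id = read_ids,
    trimmed_sequence = sequences,
    strand = best_strand,
    frame_offset = best_frame,
    internal_stop_count = as.integer(best_stops),
    length_nt = len,
    numt_flag = fail %in% c("stops_in_all_frames", "too_short"),
    fail_reason = fail
  )
}

#' Run amplicon QC on a table of reads
#'
#' Data-frame front end of the QC stage: optional primer trimming followed
#' by [screen_numt()] for every read.
#'
#' @param reads A data frame with at least `read_id` and `sequence` columns
#'   (as returned by [read_barcode_fasta()]); `sample_code` and
#'   `replicate_index` are carried through when present.
#' @param config A [qc_config()].
#' @param trim Whether to run primer trimming first (only acts when primers
#'   are configured).
#' @return A tibble with one row per read: the carried-through identifier
#'   columns plus the [screen_numt()] columns and `qc_pass` (true iff
#'   `fail_reason` is `NA`).
#' @export
qc_reads <- function(reads, config = qc_config(), trim = TRUE) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  seqs <- reads$sequence
  if (trim && (nzchar(config$primer_forward) || nzchar(config$primer_reverse))) {
    seqs <- vapply(seqs, trim_primers, character(1), config = config,
                   quiet = TRUE, USE.NAMES = FALSE)
  }
  res <- screen_numt_batch(seqs, config, reads$read_id)
  keep <- intersect(c("read_id", "sample_code", "replicate_index"), names(reads))
  out <- dplyr::left_join(reads[keep], res, by = "read_id")
  dplyr::mutate(out, qc_pass = is.na(.data$fail_reason))
}
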