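#' Alignment scoring parameters
#'
#' Linear gap scoring for the global aligner. Near-identical full-length
#' amplicons are insensitive to this choice; the defaults (+1/-1/-2) are a
#' conventional nucleotide scheme.
#'
#' @param match,mismatch,gap Per-column scores (gap is linear, applied to
#'   every gap column).
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1, gap = -2) {
  stopifnot(match > 0, mismatch <= 0, gap <= 0)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "alignment_scoring")
}

#' Percent identity by optimal global alignment
#'
#' Aligns query and reference end-to-end (Needleman-Wunsch, linear gap)
#' and reports percent identity as 100 x matches / alignment columns,
#' where columns include gap columns. An N in either sequence counts as
#' neither match nor mismatch but still occupies a column. Coverage is the
#' fraction of query positions inside the alignment, which is 100 by
#' construction for a global alignment.
#'
#' @param query,reference Nucleotide strings (ACGTN).
#' @param scoring An [alignment_scoring()].
#' @return A one-row tibble: `score`, `matches`, `aligned_columns`,
#'   `identity_pct` (rounded half-up to 2 decimals), `coverage_pct`.
#' @export
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT")$identity_pct  # 100
global_identity <- function(query, reference, scoring = alignment_scoring()) {
  stopifnot(nzchar(query), nzchar(reference))
  query <- check_alphabet(query)
  reference <- check_alphabet(reference)
  v <- .nw_align_one(query, reference, scoring$match, scoring$mismatch,
                     scoring$gap)
  tibble::tibble(
    score = v[["score"]],
    matches = as.integer(v[["matches"]]),
    aligned_columns = as.integer(v[["aligned_columns"]]),
    identity_pct = round_half_up(100 * v[["matches"]] / v[["aligned_columns"]], 2),
    coverage_pct = 100
  )
}

#' Build a reference panel from FASTA plus a taxonomy table
#'
#' The taxonomy table (TSV with columns `accession`, `species`, `genus`,
#' `family`) must cover every FASTA accession; accessions must be unique.
#'
#' @param fasta Path to the reference FASTA (headers are accessions).
#' @param taxonomy Path to the taxonomy TSV, or a data frame with the same
#'   columns.
#' @return A list of class `reference_panel` with elements `records` (a
#'   tibble: accession, species, genus, family, sequence) and
#'   `species_index` (named list species -> accessions).
#' @export
build_panel <- function(fasta, taxonomy) {
  if (is.character(taxonomy)) {
    taxonomy <- readr::read_tsv(taxonomy, show_col_types = FALSE)
  }
  taxonomy <- tibble::as_tibble(taxonomy)
  stopifnot(all(c("accession", "species", "genus", "family") %in% names(taxonomy)))
  set <- Biostrings::readBStringSet(fasta)
  acc <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in reference FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(acc, taxonomy$accession)
  if (length(missing)) {
    stop("accession(s) missing from taxonomy table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  seqs <- check_alphabet(as.character(set), acc)
  records <- dplyr::inner_join(
    tibble::tibble(accession = acc, sequence = unname(seqs)),
    taxonomy, by = "accession")
  records <- dplyr::select(records, "accession", "species", "genus",
                           "family", "sequence")
  panel <- structure(list(
    records = records,
    species_index = split(records$accession, records$species)
  ), class = "reference_panel")
  message("reference panel: ", nrow(records), " records, ",
          length(panel$species_index), " species")
  panel
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$records), " records, ",
      length(x$species_index), " species\n", sep = "")
  invisible(x)
}

#' Rank reference hits for one query sequence
#'
#' Computes global percent identity of the query against every panel
#' record and returns hits at or above the identity threshold, sorted by
#' identity descending with deterministic secondary order by accession.
#'
#' @param query Nucleotide string.
#' @param panel A [build_panel()] result.
#' @param min_identity_pct Identity threshold in percent (default 97).
#' @param scoring An [alignment_scoring()].
#' @return A tibble of hits: `accession`, `species`, `identity_pct`,
#'   `coverage_pct`, `matches`, `aligned_columns`, `score`. May be empty.
#' @export
rank_hits <- function(query, panel, min_identity_pct = 97,
                      scoring = alignment_scoring()) {
  stopifnot(inherits(panel, "reference_panel"), nrow(panel$records) > 0)
  query <- check_alphabet(query)
  m <- .nw_align_many(query, panel$records$sequence, scoring$match,
                      scoring$mismatch, scoring$gap)
  hits <- tibble::tibble(
    accession = panel$records$accession,
    species = panel$records$species,
    identity_pct = round_half_up(100 * m[, "matches"] / m[, "aligned_columns"], 2),
    coverage_pct = 100,
    matches = as.integer(m[, "matches"]),
    aligned_columns = as.integer(m[, "aligned_columns"]),
    score = m[, "score"]
  )
  hits <- dplyr::filter(hits, .data$identity_pct >= min_identity_pct)
  dplyr::arrange(hits, dplyr::desc(.data$identity_pct), .data$accession)
}

#' Call a species from ranked hits, applying the tie rule
#'
#' Collects the hits whose identity is within `tie_tolerance` of the top
#' value: if all belong to one species the read is assigned to it; if the
#' tied set spans several species the read is ambiguous; with no hits it
#' is unassigned.
#'
#' @param hits A [rank_hits()] tibble (already sorted).
#' @param tie_tolerance Identity tolerance (percentage points, on the
#'   2-decimal reported identities) defining the tied set; default 0.
#' @return A one-row tibble: `status` (`assigned`/`ambiguous`/`unassigned`),
#'   `species` (`NA` unless assigned), `identity_pct` of the best hit,
#'   `tied_species` (list column of the species in the tied set).
#' @export
call_species_for_read <- function(hits, tie_tolerance = 0) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(status = "unassigned", species = NA_character_,
                          identity_pct = NA_real_,
                          tied_species = list(character())))
  }
  top <- max(hits$identity_pct)
  tied <- unique(hits$species[hits$identity_pct >= top - tie_tolerance])
  if (length(tied) == 1) {
    tibble::tibble(status = "assigned", species = tied,
                   identity_pct = top, tied_species = list(tied))
  } else {
    tibble::tibble(status = "ambiguous", species = NA_character_,
                   identity_pct = top, tied_species = list(sort(tied)))
  }
}

#' Consensus species call per product from replicate reads
#'
#' A product sampled with up to three replicate DNA extractions gets one
#' call: unanimous assigned replicates give `assigned`; replicates assigned
#' to different species give `multi_species` (a mixed product); all
#' replicates unassigned gives `unassigned`. Ambiguous replicates are
#' recorded but do not overrule an otherwise unanimous species.
#'
#' @param replicate_calls A data frame with columns `sample_code`,
#'   `replicate_index`, `status`, `species`, `identity_pct` for one product.
#' @return A one-row tibble: `sample_code`, `status`, `species`,
#'   `best_identity_pct`, `n_replicates`, `replicate_species` (list column).
#' @export
consensus_product_call <- function(replicate_calls) {
  stopifnot(is.data.frame(replicate_calls), nrow(replicate_calls) >= 1)
  code <- unique(replicate_calls$sample_code)
  if (length(code) != 1) {
    stop("replicate calls span multiple sample codes: ",
         paste(code, collapse = ", "), call. = FALSE)
  }
  assigned <- dplyr::filter(replicate_calls, .data$status == "assigned")
  sp <- unique(assigned$species)
  if (length(sp) >= 2) {
    status <- "multi_species"; species <- NA_character_
    best <- max(assigned$identity_pct)
  } else if (length(sp) == 1) {
    status <- "assigned"; species <- sp
    best <- max(assigned$identity_pct)
  } else if (any(replicate_calls$status == "ambiguous")) {
    status <- "ambiguous"; species <- NA_character_
    best <- suppressWarnings(max(replicate_calls$identity_pct, na.rm = TRUE))
    if (!is.finite(best)) best <- NA_real_
  } else {
    status <- "unassigned"; species <- NA_character_; best <- NA_real_
  }
  tibble::tibble(
    sample_code = code, status = status, species = species,
    best_identity_pct = best,
    n_replicates = nrow(replicate_calls),
    replicate_species = list(replicate_calls$species)
  )
}

#' Assign species to QC-passed reads and form per-product consensus calls
#'
#' Data-frame front end of the assignment stage: every read is ranked
#' against the panel, called with the tie rule, and calls are reduced to
#' one consensus per `sample_code`.
#'
#' @param reads A data frame with `read_id`, `sample_code`,
#'   `replicate_index` and a sequence column (`trimmed_sequence` from
#'   [qc_reads()] or `sequence`). Reads that failed QC should be filtered
#'   out beforehand.
#' @param panel A [build_panel()] result.
#' @param min_identity_pct,tie_tolerance,scoring Passed to [rank_hits()]
#'   and [call_species_for_read()].
#' @return A list with `read_calls` (per-read tibble) and `product_calls`
#'   (per-product consensus tibble).
#' @export
assign_species <- function(reads, panel, min_identity_pct = 97,
                           tie_tolerance = 0, scoring = alignment_scoring()) {
  stopifnot(is.data.frame(reads))
  seq_col <- if ("trimmed_sequence" %in% names(reads)) "trimmed_sequence" else "sequence"
  stopifnot(seq_col %in% names(reads), "sample_code" %in% names(reads))
  rep_idx <- reads[["replicate_index"]] %||% rep(NA_integer_, nrow(reads))
  per_read <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    hits <- rank_hits(reads[[seq_col]][i], panel, min_identity_pct, scoring)
    call <- call_species_for_read(hits, tie_tolerance)
    dplyr::bind_cols(
      tibble::tibble(read_id = reads$read_id[i],
                     sample_code = reads$sample_code[i],
                     replicate_index = rep_idx[i]),
      call)
  })
  product <- per_read |>
    split(per_read$sample_code) |>
    purrr::map_dfr(consensus_product_call)
  list(read_calls = per_read, product_calls = product)
}
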