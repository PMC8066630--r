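# Stop codons read in forward frame 0 under a genetic code table.
stop_codons_of <- function(genetic_code_id = 2L) {
  code <- lookup_genetic_code(genetic_code_id)
  names(code)[code == "*"]
}

#' Simulation configuration
#'
#' Defaults emulate the packaged survey's regime: a 16-species reference
#' panel of ~650 nt COI-like amplicons, three replicate extractions per
#' product, 60 products, queries at 98.5% identity to their generating
#' reference (the survey's observed identities span 98.17-99.85%), a
#' mislabeling rate of 0.35 (the survey's regional rates span roughly
#' 32-40%), and no NUMT co-amplification (none was observed; decoys are
#' opt-in via `numt_fraction`).
#'
#' @param seed Integer seed; every generator is deterministic under it.
#' @param n_species Number of panel species.
#' @param sequence_length_nt Amplicon length (default 650).
#' @param min_interspecies_divergence Minimum pairwise divergence between
#'   panel species as a fraction (default 0.10).
#' @param query_identity Target identity of generated query reads to their
#'   reference, as a fraction (default 0.985).
#' @param mislabel_rate Fraction of products whose declared label is
#'   swapped to another species' trade name. The generator fixes the
#'   number of mislabeled products at `round(n_products * mislabel_rate)`
#'   so the realized rate equals the nominal one; which products are
#'   mislabeled is random.
#' @param n_products Number of products in a simulated survey.
#' @param replicates_per_product Replicate reads per product (1-3).
#' @param numt_fraction Fraction of reads replaced by NUMT decoys.
#' @param n_umbrella Number of auto-generated umbrella trade names, each
#'   covering two species at genus rank.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_species = 16L,
                              sequence_length_nt = 650L,
                              min_interspecies_divergence = 0.10,
                              query_identity = 0.985,
                              mislabel_rate = 0.35,
                              n_products = 60L,
                              replicates_per_product = 3L,
                              numt_fraction = 0,
                              n_umbrella = 2L) {
  stopifnot(n_species >= 1, sequence_length_nt >= 30,
            min_interspecies_divergence >= 0, min_interspecies_divergence <= 1,
            query_identity > 0, query_identity <= 1,
            mislabel_rate >= 0, mislabel_rate <= 1,
            numt_fraction >= 0, numt_fraction <= 1,
            replicates_per_product %in% 1:3)
  if (mislabel_rate > 0 && n_species < 2) {
    stop("mislabel_rate > 0 requires at least 2 species", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 sequence_length_nt = as.integer(sequence_length_nt),
                 min_interspecies_divergence = min_interspecies_divergence,
                 query_identity = query_identity,
                 mislabel_rate = mislabel_rate,
                 n_products = as.integer(n_products),
                 replicates_per_product = as.integer(replicates_per_product),
                 numt_fraction = numt_fraction,
                 n_umbrella = as.integer(n_umbrella)),
            class = "simulation_config")
}

# One stop-free coding sequence: codons drawn uniformly from the non-stop
# codon set of the vertebrate mitochondrial code, truncated to the exact
# requested length (a trailing partial codon cannot introduce a frame-0
# stop).
random_coding_sequence <- function(length_nt, genetic_code_id = 2L) {
  code <- lookup_genetic_code(genetic_code_id)
  pool <- names(code)[code != "*"]
  n_codon <- ceiling(length_nt / 3)
  s <- paste(sample(pool, n_codon, replace = TRUE), collapse = "")
  substr(s, 1, length_nt)
}

#' Simulate a taxonomy-annotated reference panel
#'
#' Generates `n_species` stop-free coding sequences under the vertebrate
#' mitochondrial code and verifies by direct pairwise global alignment
#' that every species pair diverges by at least
#' `min_interspecies_divergence`; offending sequences are regenerated a
#' bounded number of times.
#'
#' @param config A [simulation_config()].
#' @return A list: `panel` (a `reference_panel`), `taxonomy` (tibble) and
#'   `truth` (per-record generating metadata).
#' @export
simulate_panel <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_species
  len <- config$sequence_length_nt
  seqs <- vapply(seq_len(n), function(i) random_coding_sequence(len),
                 character(1))
  max_ident <- 100 * (1 - config$min_interspecies_divergence)
  for (attempt in seq_len(20)) {
    ok <- TRUE
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        m <- .nw_align_many(seqs[i], seqs[(i + 1):n], 1, -1, -2)
        ident <- 100 * m[, "matches"] / m[, "aligned_columns"]
        bad <- which(ident > max_ident)
        if (length(bad)) {
          ok <- FALSE
          for (j in i + bad) seqs[j] <- random_coding_sequence(len)
        }
      }
    }
    if (ok) break
    if (attempt == 20) {
      stop("could not achieve the requested interspecies divergence",
           call. = FALSE)
    }
  }
  genus <- sprintf("Simgenus%02d", seq_len(n))
  species <- paste(genus, sprintf("simspecies%02d", seq_len(n)))
  taxonomy <- tibble::tibble(accession = sprintf("SIMACC%03d", seq_len(n)),
                             species = species, genus = genus,
                             family = "Simfamilia")
  records <- dplyr::mutate(taxonomy, sequence = seqs)
  panel <- structure(list(
    records = dplyr::select(records, "accession", "species", "genus",
                            "family", "sequence"),
    species_index = split(records$accession, records$species)
  ), class = "reference_panel")
  list(panel = panel,
       taxonomy = dplyr::select(taxonomy, "species", "genus", "family"),
       truth = tibble::tibble(accession = taxonomy$accession,
                              species = species, length_nt = nchar(seqs)))
}

#' Mutate a sequence to a target percent identity
#'
#' Applies exactly `round(length * (1 - target_identity))` substitutions
#' at distinct positions (no indels). With `preserve_frame = TRUE`,
#' substitutions that would create a forward frame-0 stop codon are
#' resampled, so the mutant still passes NUMT screening.
#'
#' @param reference Nucleotide string.
#' @param target_identity Fraction in (0, 1].
#' @param seed Optional integer seed (`NULL` uses the current RNG state).
#' @param preserve_frame Avoid creating in-frame stop codons.
#' @param genetic_code_id Code table used for the stop set (default 2).
#' @return The mutated sequence, with attribute `n_mutations`.
#' @export
mutate_to_identity <- function(reference, target_identity, seed = NULL,
                               preserve_frame = TRUE, genetic_code_id = 2L) {
  stopifnot(target_identity > 0, target_identity <= 1)
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(reference)
  k <- as.integer(round_half_up(len * (1 - target_identity)))
  if (k > len) stop("requested mutations exceed sequence length", call. = FALSE)
  if (k == 0) return(structure(reference, n_mutations = 0L))
  stops <- stop_codons_of(genetic_code_id)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(reference, "")[[1]]
  available <- seq_len(len)
  done <- 0L
  guard <- 0L
  while (done < k) {
    guard <- guard + 1L
    if (guard > 50L * k || length(available) == 0) {
      stop("could not place the requested substitutions without stops",
           call. = FALSE)
    }
    idx <- if (length(available) == 1) available else sample(available, 1)
    alts <- sample(setdiff(bases, chars[idx]))
    placed <- FALSE
    for (b in alts) {
      old <- chars[idx]
      chars[idx] <- b
      if (preserve_frame) {
        codon_start <- idx - (idx - 1) %% 3
        codon <- paste(chars[codon_start:min(codon_start + 2, len)],
                       collapse = "")
        if (nchar(codon) == 3 && codon %in% stops) {
          chars[idx] <- old
          next
        }
      }
      placed <- TRUE
      break
    }
    if (placed) {
      done <- done + 1L
      available <- setdiff(available, idx)
    } else {
      available <- setdiff(available, idx)
    }
  }
  structure(paste(chars, collapse = ""), n_mutations = k)
}

# Overwrite codons so that every one of the six frame/strand combinations
# that still lacks an internal stop gains one. Forward-frame stops are
# written as TAA in the left half; reverse-frame stops are written as TTA
# (the reverse complement of TAA) in the right half, at positions chosen
# so the target frame reads them in-frame. Regions are spaced so writes
# cannot clobber each other.
ensure_all_frame_stops <- function(sequence, genetic_code_id = 2L) {
  len <- nchar(sequence)
  stopifnot(len >= 120)
  combos <- tidyr::expand_grid(strand = c("forward", "reverse"),
                               frame_offset = 0:2)
  for (i in seq_len(nrow(combos))) {
    st <- combos$strand[i]
    f <- combos$frame_offset[i]
    if (internal_stops(translate_dna(sequence, f, st, genetic_code_id)) > 0) next
    anchor <- 30 + 12 * (i - 1)
    if (st == "forward") {
      # codon starts at 1-based positions f+1, f+4, ...
      p <- f + 1 + 3 * ceiling((anchor - f) / 3)
      substr(sequence, p, p + 2) <- "TAA"
    } else {
      # 0-based reverse-complement position q (q %% 3 == f) maps to
      # forward 1-based start s = len - q - 2
      q <- f + 3 * ceiling(anchor / 3)
      s <- len - q - 2
      substr(sequence, s, s + 2) <- "TTA"
    }
  }
  bad <- purrr::map2_int(combos$strand, combos$frame_offset, function(st, f) {
    internal_stops(translate_dna(sequence, f, st, genetic_code_id))
  })
  if (any(bad == 0)) {
    stop("failed to place stop codons in all six frames", call. = FALSE)
  }
  sequence
}

#' Construct a NUMT decoy from a clean reference
#'
#' Builds a sequence guaranteed to fail [screen_numt()]: `stop_insert`
#' places stop codons in all six frame/strand combinations; `frameshift`
#' deletes one nucleotide mid-sequence and then guarantees stops in every
#' remaining frame; `truncate` returns a fragment (at most 550 nt and at
#' most 85% of the reference length) below the 600 nt NUMT size heuristic.
#'
#' @param reference Nucleotide string that itself passes [screen_numt()].
#' @param seed Optional seed.
#' @param mode `"stop_insert"`, `"frameshift"` or `"truncate"`.
#' @param genetic_code_id Code table (default 2).
#' @return The decoy sequence.
#' @export
make_numt_decoy <- function(reference, seed = NULL,
                            mode = c("stop_insert", "frameshift", "truncate"),
                            genetic_code_id = 2L) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  len <- nchar(reference)
  switch(mode,
    truncate = substr(reference, 1, min(550L, floor(len * 0.85))),
    stop_insert = ensure_all_frame_stops(reference, genetic_code_id),
    frameshift = {
      cut <- sample(seq(len %/% 3, 2 * len %/% 3), 1)
      shifted <- paste0(substr(reference, 1, cut - 1),
                        substr(reference, cut + 1, len))
      ensure_all_frame_stops(shifted, genetic_code_id)
    })
}

#' Simulate a whole market survey with known ground truth
#'
#' Generates a reference panel, an auto-generated trade-name universe (one
#' species-rank name per species plus `n_umbrella` genus-rank umbrella
#' names each covering two species), product metadata with regions, retail
#' types and categories drawn uniformly, replicate query reads at the
#' configured identity, optional NUMT decoy reads, and the per-product
#' ground truth. Exactly `round(n_products * mislabel_rate)` products are
#' mislabeled: their declared label is swapped to the species-rank name of
#' a different species, so the intended verdict is misdescribed.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, reads FASTA, products
#'   TSV, rules TSV and ground-truth JSON are written there.
#' @return A list: `reads`, `products`, `rules`, `panel`, `taxonomy`,
#'   `truth`, `config`.
#' @export
simulate_survey <- function(config = simulation_config(), outdir = NULL) {
  sim <- simulate_panel(config)
  set.seed(config$seed + 1L)
  panel <- sim$panel
  n <- config$n_products
  species <- panel$records$species
  if (config$mislabel_rate > 0 && length(species) < 2) {
    stop("mislabel_rate > 0 requires a panel with at least 2 species",
         call. = FALSE)
  }

  name_of <- stats::setNames(sprintf("simname%02d", seq_along(species)), species)
  rules <- tibble::tibble(trade_name = unname(name_of), rank = "species",
                          taxon = species, listed = TRUE,
                          source = "simulated")
  if (config$n_umbrella > 0 && length(species) >= 2) {
    umb <- purrr::map_dfr(seq_len(config$n_umbrella), function(j) {
      pick <- ((2 * (j - 1)) %% length(species)) + c(0, 1) %% length(species) + 1
      pick <- ((pick - 1) %% length(species)) + 1
      tibble::tibble(trade_name = sprintf("umbrella%02d", j), rank = "genus",
                     taxon = genus_of(species[unique(pick)]), listed = TRUE,
                     source = "simulated umbrella")
    })
    rules <- dplyr::bind_rows(rules, umb)
  }
  rules <- load_name_rules(rules)

  true_species <- sample(species, n, replace = TRUE)
  declared <- unname(name_of[true_species])
  n_mis <- as.integer(round_half_up(n * config$mislabel_rate))
  mislabeled <- sort(sample.int(n, n_mis))
  for (i in mislabeled) {
    declared[i] <- name_of[sample(setdiff(species, true_species[i]), 1)]
  }
  products <- tibble::tibble(
    sample_code = sprintf("SIM%04d", seq_len(n)),
    region = sample(c("north", "central", "south"), n, replace = TRUE),
    retail_type = sample(c("restaurant", "takeaway"), n, replace = TRUE),
    category = sample(c("white_fish", "tuna", "roe"), n, replace = TRUE),
    menu_label = declared
  )

  ref_of <- stats::setNames(panel$records$sequence, species)
  reads <- tidyr::expand_grid(product = seq_len(n),
                              replicate_index = seq_len(config$replicates_per_product))
  n_reads <- nrow(reads)
  n_decoy <- as.integer(round_half_up(n_reads * config$numt_fraction))
  decoy_rows <- if (n_decoy > 0) sort(sample.int(n_reads, n_decoy)) else integer()
  decoy_modes <- c("stop_insert", "frameshift", "truncate")
  seqs <- character(n_reads)
  n_mut <- integer(n_reads)
  is_decoy <- logical(n_reads)
  for (r in seq_len(n_reads)) {
    ref <- ref_of[[true_species[reads$product[r]]]]
    if (r %in% decoy_rows) {
      seqs[r] <- make_numt_decoy(ref, mode = sample(decoy_modes, 1))
      is_decoy[r] <- TRUE
      n_mut[r] <- NA_integer_
    } else {
      mut <- mutate_to_identity(ref, config$query_identity,
                                preserve_frame = TRUE)
      seqs[r] <- mut
      n_mut[r] <- attr(mut, "n_mutations")
    }
  }
  reads_tbl <- tibble::tibble(
    read_id = paste0(products$sample_code[reads$product], "|",
                     reads$replicate_index),
    sample_code = products$sample_code[reads$product],
    replicate_index = reads$replicate_index,
    sequence = seqs,
    is_decoy = is_decoy,
    n_mutations = n_mut
  )

  intended <- ifelse(seq_len(n) %in% mislabeled, "misdescribed", "compliant")
  truth <- tibble::tibble(
    sample_code = products$sample_code,
    true_species = true_species,
    declared_label = declared,
    intended_verdict = intended
  )

  out <- list(reads = reads_tbl, products = products, rules = rules,
              panel = panel, taxonomy = sim$taxonomy, truth = truth,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste0(">", reads_tbl$read_id, "\n", reads_tbl$sequence),
               file.path(outdir, "reads.fasta"))
    writeLines(paste0(">", panel$records$accession, "\n",
                      panel$records$sequence),
               file.path(outdir, "panel.fasta"))
    readr::write_tsv(products, file.path(outdir, "products.tsv"))
    readr::write_tsv(dplyr::select(panel$records, -"sequence"),
                     file.path(outdir, "panel_taxonomy.tsv"))
    readr::write_tsv(tibble::as_tibble(rules), file.path(outdir, "rules.tsv"))
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Run the full authentication pipeline on a simulated or real survey
#'
#' QC screens every read, QC-passed reads are assigned against the panel,
#' per-product consensus calls are made, compliance verdicts are derived
#' from the menu labels under the rule set, and stratified rates are
#' computed.
#'
#' @param reads Read table (`read_id`, `sample_code`, `replicate_index`,
#'   `sequence`).
#' @param products Product table (`sample_code`, `region`, `retail_type`,
#'   `category`, `menu_label`, optionally `declared_name`).
#' @param panel A `reference_panel`.
#' @param rules A `name_rules` tibble.
#' @param taxonomy Species taxonomy for rank evaluation.
#' @param qc A [qc_config()]; the default is used when `NULL`.
#' @param min_identity_pct,tie_tolerance Assignment parameters.
#' @return A list: `qc`, `read_calls`, `product_calls`, `verdicts`,
#'   `summary`.
#' @export
run_pipeline <- function(reads, products, panel, rules, taxonomy,
                         qc = NULL, min_identity_pct = 97, tie_tolerance = 0) {
  qc <- qc %||% qc_config()
  qc_tbl <- qc_reads(reads, qc, trim = FALSE)
  passed <- dplyr::filter(qc_tbl, .data$qc_pass)
  if (nrow(passed) == 0) stop("no reads passed QC", call. = FALSE)
  asg <- assign_species(passed, panel, min_identity_pct, tie_tolerance)
  calls <- asg$product_calls
  # products whose every read failed QC get an explicit unassigned call
  absent <- setdiff(products$sample_code, calls$sample_code)
  if (length(absent)) {
    calls <- dplyr::bind_rows(calls, tibble::tibble(
      sample_code = absent, status = "unassigned", species = NA_character_,
      best_identity_pct = NA_real_, n_replicates = 0L,
      replicate_species = list(character())))
  }
  verdicts <- call_compliance(products, calls, rules, taxonomy)
  summary <- stratified_rates(verdicts, products,
                              dplyr::select(calls, "sample_code", "status",
                                            "species"))
  list(qc = qc_tbl, read_calls = asg$read_calls, product_calls = calls,
       verdicts = verdicts, summary = summary)
}
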