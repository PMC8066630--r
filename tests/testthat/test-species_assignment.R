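test_that("global identity is exact on constructed pairs", {
  set.seed(21)
  x <- random_dna(650)
  self <- global_identity(x, x)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$coverage_pct, 100)
  expect_equal(self$matches, 650L)

  # two substitutions, no gaps: 648/650 = 99.6923 -> 99.69
  y <- x
  substr(y, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(x, 100, 100))[1]
  substr(y, 500, 500) <- setdiff(c("A", "C", "G", "T"), substr(x, 500, 500))[1]
  two <- global_identity(x, y)
  expect_equal(two$matches, 648L)
  expect_equal(two$aligned_columns, 650L)
  expect_equal(two$identity_pct, 99.69)

  # a deletion forces a gap column: ACGT vs AGT -> 3 matches over 4 columns
  gap <- global_identity("ACGT", "AGT")
  expect_equal(gap$score, 1)
  expect_equal(gap$matches, 3L)
  expect_equal(gap$aligned_columns, 4L)

  # N occupies a column but is neither match nor mismatch
  amb <- global_identity("ACGN", "ACGT")
  expect_equal(amb$matches, 3L)
  expect_equal(amb$aligned_columns, 4L)
  expect_equal(amb$identity_pct, 75)
})

test_that("DP alignment score matches the brute-force enumeration oracle", {
  set.seed(22)
  for (i in 1:150) {
    q <- random_dna(sample(0:8, 1) + 1)
    r <- random_dna(sample(0:8, 1) + 1)
    expect_equal(global_identity(q, r)$score, brute_force_score(q, r),
                 info = paste(q, r))
  }
  # including ambiguous bases
  for (i in 1:50) {
    q <- random_dna(sample(1:6, 1), alphabet = c("A", "C", "G", "T", "N"))
    r <- random_dna(sample(1:6, 1), alphabet = c("A", "C", "G", "T", "N"))
    expect_equal(global_identity(q, r)$score, brute_force_score(q, r),
                 info = paste(q, r))
  }
})

test_that("identity is symmetric and maximal on self", {
  set.seed(23)
  for (i in 1:25) {
    q <- random_dna(sample(5:40, 1))
    r <- random_dna(sample(5:40, 1))
    a <- global_identity(q, r)
    b <- global_identity(r, q)
    expect_equal(a$score, b$score)
    expect_equal(a$identity_pct, b$identity_pct)
    expect_equal(global_identity(q, q)$identity_pct, 100)
  }
})

make_test_panel <- function(n_species = 3, len = 600, seed = 24) {
  sim <- simulate_panel(simulation_config(seed = seed, n_species = n_species,
                                          sequence_length_nt = len))
  sim$panel
}

test_that("panels enforce referential integrity and index species", {
  dir <- withr::local_tempdir()
  fasta <- file.path(dir, "panel.fasta")
  tax <- file.path(dir, "tax.tsv")
  set.seed(25)
  seqs <- vapply(1:4, function(i) random_dna(500), character(1))
  write_fasta(stats::setNames(seqs, paste0("ACC", 1:4)), fasta)
  taxonomy <- tibble::tibble(
    accession = paste0("ACC", 1:4),
    species = c("Thunnus thynnus", "Thunnus albacares", "Sparus aurata",
                "Sparus aurata"),
    genus = c("Thunnus", "Thunnus", "Sparus", "Sparus"),
    family = c("Scombridae", "Scombridae", "Sparidae", "Sparidae"))
  readr::write_tsv(taxonomy, tax)

  panel <- suppressMessages(build_panel(fasta, tax))
  expect_equal(nrow(panel$records), 4)
  expect_equal(length(panel$species_index), 3)
  # one species under two accessions: index maps it to both
  expect_setequal(panel$species_index[["Sparus aurata"]], c("ACC3", "ACC4"))

  # accession absent from taxonomy
  readr::write_tsv(taxonomy[1:3, ], tax)
  expect_error(suppressMessages(build_panel(fasta, tax)), "ACC4")

  # duplicate accession in FASTA
  write_fasta(stats::setNames(seqs, c("ACC1", "ACC1", "ACC3", "ACC4")), fasta)
  expect_error(suppressMessages(build_panel(fasta, tax)), "duplicate")
})

test_that("hit ranking is correct, thresholded and deterministic", {
  panel <- make_test_panel(3, 600)
  q <- panel$records$sequence[2]
  hits <- rank_hits(q, panel, min_identity_pct = 0)
  expect_equal(hits$accession[1], panel$records$accession[2])
  expect_equal(hits$identity_pct[1], 100)

  # threshold excludes non-exact matches
  mut <- mutate_to_identity(q, 0.99, seed = 1)
  expect_equal(nrow(rank_hits(mut, panel, min_identity_pct = 100)), 0)

  # a query mutated from species 2 at ~99% ranks species 2 first
  hits_mut <- rank_hits(mut, panel)
  expect_equal(hits_mut$species[1], panel$records$species[2])

  # determinism
  expect_identical(rank_hits(q, panel, 0), rank_hits(q, panel, 0))
})

test_that("the tie rule assigns, flags ambiguity, or leaves unassigned", {
  hits1 <- tibble::tibble(accession = c("A1", "A2"),
                          species = c("Thunnus albacares", "Thunnus albacares"),
                          identity_pct = c(99.54, 99.50))
  c1 <- call_species_for_read(hits1, tie_tolerance = 0)
  expect_equal(c1$status, "assigned")
  expect_equal(c1$species, "Thunnus albacares")
  expect_equal(c1$identity_pct, 99.54)

  # identical top identities across two species -> ambiguous
  hits2 <- tibble::tibble(accession = c("A1", "A2"),
                          species = c("Thunnus albacares", "Thunnus obesus"),
                          identity_pct = c(99.54, 99.54))
  c2 <- call_species_for_read(hits2, tie_tolerance = 0)
  expect_equal(c2$status, "ambiguous")
  expect_setequal(c2$tied_species[[1]], c("Thunnus albacares", "Thunnus obesus"))

  # tolerance widens the tied set
  c3 <- call_species_for_read(hits1, tie_tolerance = 0.1)
  expect_equal(c3$status, "assigned")
  c4 <- call_species_for_read(
    dplyr::mutate(hits2, identity_pct = c(99.54, 99.50)), tie_tolerance = 0.1)
  expect_equal(c4$status, "ambiguous")

  expect_equal(call_species_for_read(hits1[0, ])$status, "unassigned")
})

test_that("consensus calls follow the replicate design", {
  reps <- function(species, status = "assigned", code = "P1") {
    tibble::tibble(sample_code = code,
                   replicate_index = seq_along(species),
                   status = status, species = species,
                   identity_pct = c(99.1, 99.5, 99.3)[seq_along(species)])
  }
  # three unanimous replicates
  c1 <- consensus_product_call(reps(rep("Thunnus albacares", 3)))
  expect_equal(c1$status, "assigned")
  expect_equal(c1$species, "Thunnus albacares")
  expect_equal(c1$best_identity_pct, 99.5)

  # single-replicate product assigns from that call
  c2 <- consensus_product_call(reps("Sparus aurata"))
  expect_equal(c2$status, "assigned")
  expect_equal(c2$species, "Sparus aurata")

  # replicates disagreeing on species -> multi_species
  c3 <- consensus_product_call(reps(c("Sparus aurata", "Dicentrarchus labrax")))
  expect_equal(c3$status, "multi_species")

  # an ambiguous replicate does not overrule a unanimous species
  mixed <- dplyr::bind_rows(reps(rep("Sparus aurata", 2)),
                            tibble::tibble(sample_code = "P1",
                                           replicate_index = 3L,
                                           status = "ambiguous",
                                           species = NA_character_,
                                           identity_pct = 99.9))
  c4 <- consensus_product_call(mixed)
  expect_equal(c4$status, "assigned")
  expect_equal(c4$species, "Sparus aurata")

  # all replicates unassigned
  c5 <- consensus_product_call(
    tibble::tibble(sample_code = "P1", replicate_index = 1:2,
                   status = "unassigned", species = NA_character_,
                   identity_pct = NA_real_))
  expect_equal(c5$status, "unassigned")

  expect_error(consensus_product_call(
    dplyr::bind_rows(reps("Sparus aurata", code = "P1"),
                     reps("Sparus aurata", code = "P2"))),
    "multiple sample codes")
})

test_that("simulated consensus recovers the generating species", {
  sim <- simulate_survey(simulation_config(seed = 26, n_species = 5,
                                           sequence_length_nt = 480,
                                           n_products = 12,
                                           replicates_per_product = 2,
                                           mislabel_rate = 0))
  qc <- qc_reads(sim$reads, qc_config(min_length_nt = 400, max_length_nt = 500,
                                      expected_window = c(400, 500)))
  asg <- assign_species(qc[qc$qc_pass, ], sim$panel)
  got <- dplyr::left_join(asg$product_calls, sim$truth, by = "sample_code")
  expect_true(all(got$status == "assigned"))
  expect_true(all(got$species == got$true_species))
})
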