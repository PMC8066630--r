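test_that("FASTA reading parses records, headers and alphabet", {
  path <- withr::local_tempfile(fileext = ".fasta")
  set.seed(7)
  seqs <- c("MIL1T|1" = random_dna(650), "MIL1T|2" = random_dna(640))
  write_fasta(seqs, path)
  reads <- read_barcode_fasta(path)
  expect_equal(nrow(reads), 2)
  expect_equal(nchar(reads$sequence), c(650, 640))
  expect_equal(reads$sample_code, c("MIL1T", "MIL1T"))
  expect_equal(reads$replicate_index, c(1L, 2L))

  # U is converted to T, case is folded
  write_fasta(c("s|1" = "acgu"), path)
  expect_equal(read_barcode_fasta(path)$sequence, "ACGT")

  # empty file -> empty table
  writeLines(character(), path)
  expect_equal(nrow(read_barcode_fasta(path)), 0)

  # non-IUPAC character named by record
  write_fasta(c("good|1" = "ACGT", "bad|1" = "ACXT"), path)
  expect_error(read_barcode_fasta(path), "bad\\|1")
})

test_that("primer trimming removes matched primers and tolerates mismatches", {
  set.seed(8)
  body <- random_dna(650)
  primer <- "AACCGGTT"
  cfg0 <- qc_config(primer_forward = primer, max_primer_mismatch = 0)
  expect_equal(trim_primers(paste0(primer, body), cfg0, quiet = TRUE), body)

  # no occurrence: unchanged, with a notice
  expect_message(out <- trim_primers(body, cfg0), "unchanged")
  expect_equal(out, body)

  # one mismatch in the primer: trimmed at tolerance 1, not at 0
  primer_mm <- paste0("AACCGGAT")  # last-but-one base differs
  seq_mm <- paste0(primer_mm, body)
  cfg1 <- qc_config(primer_forward = primer, max_primer_mismatch = 1)
  expect_equal(trim_primers(seq_mm, cfg1, quiet = TRUE), body)
  expect_equal(suppressMessages(trim_primers(seq_mm, cfg0)), seq_mm)

  # brute-force offset scan agrees with the trimming position
  scan <- function(p, x, k) {
    pv <- strsplit(p, "")[[1]]
    for (s in seq_len(nchar(x) - length(pv) + 1)) {
      w <- strsplit(substr(x, s, s + length(pv) - 1), "")[[1]]
      if (sum(w != pv) <= k) return(s)
    }
    NA_integer_
  }
  pos <- scan(primer, seq_mm, 1)
  expect_equal(trim_primers(seq_mm, cfg1, quiet = TRUE),
               substr(seq_mm, pos + nchar(primer), nchar(seq_mm)))

  # reverse primer trimmed at the 3' end via its reverse complement
  rev_primer <- "TTGGCCAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_primer)))
  cfg2 <- qc_config(primer_reverse = rev_primer, max_primer_mismatch = 0)
  expect_equal(trim_primers(paste0(body, rc), cfg2, quiet = TRUE), body)

  # trimming that destroys the sequence errors
  expect_error(trim_primers(paste0(primer, "ACGTACGT"), cfg0, quiet = TRUE),
               "50 nt")
})

test_that("translation follows the selected genetic code, frame and strand", {
  expect_equal(translate_dna("ATGGCC"), "MA")
  # AGA/AGG: stops in the vertebrate mitochondrial code, Arg in the standard
  expect_equal(translate_dna("AGA"), "*")
  expect_equal(translate_dna("AGG"), "*")
  expect_equal(translate_dna("AGA", genetic_code_id = 1), "R")
  # TGA is Trp, ATA is Met under the mitochondrial code
  expect_equal(translate_dna("TGAATA"), "WM")
  # frame 1 drops the leading base
  expect_equal(translate_dna("ATGG", frame_offset = 1), "W")
  # reverse strand translates the reverse complement
  expect_equal(translate_dna("GGCCAT", strand = "reverse"), "MA")
  # codons containing N translate to X, never to a stop
  expect_equal(translate_dna("ATGNNC"), "MX")
  expect_error(translate_dna("ATG", genetic_code_id = 99), "supported")
})

test_that("translated length is floor((len - frame)/3) for every frame", {
  set.seed(9)
  for (len in c(3, 7, 20, 100)) {
    s <- random_dna(len)
    for (f in 0:2) {
      expect_equal(nchar(translate_dna(s, f)), (len - f) %/% 3)
    }
  }
})

test_that("NUMT screening passes clean amplicons and flags defects", {
  clean <- test_coding_sequence(650)
  res <- screen_numt(clean)
  expect_false(res$numt_flag)
  expect_equal(res$internal_stop_count, 0L)
  expect_equal(res$strand, "forward")
  expect_equal(res$frame_offset, 0L)

  # stop-free but below the 600 nt NUMT-size heuristic
  short <- substr(clean, 1, 550)
  res_s <- screen_numt(short)
  expect_true(res_s$numt_flag)
  expect_equal(res_s$fail_reason, "too_short")

  # over-long sequences fail without the NUMT flag
  long <- paste0(clean, test_coding_sequence(90, seed = 5))
  res_l <- screen_numt(long)
  expect_equal(res_l$fail_reason, "too_long")
  expect_false(res_l$numt_flag)

  # N-rich sequences fail as ambiguous, not as NUMTs
  n_rich <- paste0(strrep("N", 20), substr(clean, 21, 650))
  res_n <- screen_numt(n_rich)
  expect_equal(res_n$fail_reason, "ambiguous_bases")
  expect_false(res_n$numt_flag)

  # a tolerable amount of N passes
  one_n <- paste0("N", substr(clean, 2, 650))
  expect_true(is.na(screen_numt(one_n)$fail_reason))

  # in-window warning: lengths inside hard bounds but outside 636-655
  mid <- substr(clean, 1, 620)
  expect_warning(res_m <- screen_numt(mid), "expected window")
  expect_false(res_m$numt_flag)
})

test_that("stops in every frame yield the stops_in_all_frames NUMT flag", {
  clean <- test_coding_sequence(650)
  decoy <- make_numt_decoy(clean, seed = 1, mode = "stop_insert")
  res <- screen_numt(decoy)
  expect_true(res$numt_flag)
  expect_equal(res$fail_reason, "stops_in_all_frames")
  expect_gte(res$internal_stop_count, 1L)
})

test_that("frame selection is minimal and reverse-complement symmetric", {
  set.seed(10)
  for (i in 1:5) {
    s <- random_dna(300)
    frames <- coiauth:::six_frame_stops(s)
    res <- suppressWarnings(screen_numt(s, qc_config(min_length_nt = 100,
                                                     max_length_nt = 400)))
    expect_equal(res$internal_stop_count, min(frames$stops))

    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    res_rc <- suppressWarnings(screen_numt(rc, qc_config(min_length_nt = 100,
                                                         max_length_nt = 400)))
    expect_equal(res_rc$numt_flag, res$numt_flag)
    expect_equal(res_rc$internal_stop_count, res$internal_stop_count)
  }
})

test_that("qc_reads carries read identity through and flags failures", {
  clean <- test_coding_sequence(650)
  reads <- tibble::tibble(
    read_id = c("P1|1", "P1|2", "P2|1"),
    sample_code = c("P1", "P1", "P2"),
    replicate_index = c(1L, 2L, 1L),
    sequence = c(clean, substr(clean, 1, 550),
                 make_numt_decoy(clean, seed = 2, mode = "frameshift")))
  qc <- qc_reads(reads)
  expect_equal(qc$qc_pass, c(TRUE, FALSE, FALSE))
  expect_equal(qc$fail_reason, c(NA, "too_short", "stops_in_all_frames"))
  expect_equal(qc$sample_code, reads$sample_code)
})
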