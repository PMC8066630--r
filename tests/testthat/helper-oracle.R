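# Brute-force global-alignment score: plain recursion over the three
# extension moves, no memoization -- an enumeration of every gapped
# alignment, independent of the dynamic-programming implementation.
# Feasible only for tiny strings.
brute_force_score <- function(q, r, match = 1, mismatch = -1, gap = -2) {
  qs <- strsplit(q, "")[[1]]
  rs <- strsplit(r, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L) {
      s <- if (qs[i] == "N" || rs[j] == "N") 0
           else if (qs[i] == rs[j]) match else mismatch
      best <- max(best, rec(i - 1L, j - 1L) + s)
    }
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(qs), length(rs))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

write_fasta <- function(seqs, path, width = 60) {
  lines <- unlist(purrr::map2(names(seqs), unname(seqs), function(id, s) {
    body <- substring(s, seq(1, nchar(s), width),
                      pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  path
}

# A stop-free ~650 nt coding sequence for QC tests.
test_coding_sequence <- function(len = 650, seed = 101) {
  cfg <- simulation_config(seed = seed, n_species = 1,
                           sequence_length_nt = len,
                           mislabel_rate = 0, n_umbrella = 0)
  simulate_panel(cfg)$panel$records$sequence[1]
}
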