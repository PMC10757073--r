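# Independent pure-R Smith-Waterman score oracle (full-matrix DP, written
# against the recurrence directly; no shared code with the package kernel).
sw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      h <- max(0, H[i, j] + s, H[i, j + 1] + gap, H[i + 1, j] + gap)
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

# Biostrings as a second, fully independent local-alignment score oracle
# (linear gap model: opening 0, extension 1 per gap column).
sw_score_biostrings <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1))
}

# all sequences over {A,C} of lengths 1..max_len
ac_universe <- function(max_len) {
  out <- character()
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C")), l))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

random_seq_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
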