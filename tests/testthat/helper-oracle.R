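# Independent pure-R oracle for the ungapped aligner: exhaustive Hamming
# scan of one read over every hairpin at every offset, keeping placements
# at the minimal mismatch count <= max_mm. Characters outside {A,C,G,T}
# never match.
oracle_align_one <- function(read, sequences, max_mm = 2L) {
  rd <- strsplit(read, "")[[1]]
  L <- length(rd)
  hits <- list()
  for (hid in names(sequences)) {
    hp <- strsplit(sequences[[hid]], "")[[1]]
    H <- length(hp)
    if (L > H) next
    for (s in seq_len(H - L + 1L)) {
      win <- hp[s:(s + L - 1L)]
      mm <- sum(!(rd == win & rd %in% c("A", "C", "G", "T")))
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(
          hairpin_id = hid, start = s, mismatches = mm,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(hairpin_id = character(0), start = integer(0),
                      mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out[out$mismatches == min(out$mismatches), , drop = FALSE]
}

# Small fixed two-hairpin reference used across unit tests. The mature
# arms sit at known coordinates so offsets are easy to reason about.
tiny_reference <- function() {
  hp1 <- paste0("GGGGG", "ACGTACGTAACCGGTTACGATCG", "TTTTTCCCCCAAAAAGGGGGTTTTTCCCCCAAAAA")
  hp2 <- paste0("AAAAAAAAAA", "TGCATGCATTGGCCAATGCTAG", "GGGGGCCCCCTTTTTAAAAACCCCCGGGGGTTTTT")
  hairpin_reference(
    c(hp1 = hp1, hp2 = hp2),
    data.frame(hairpin_id = c("hp1", "hp2"),
               mature_id = c("mat1", "mat2"),
               start = c(6L, 11L), end = c(28L, 32L)))
}

# Random reference + reads for property tests (independent of the
# package's own simulator).
random_sequences <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

mutate_bases <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  paste(s, collapse = "")
}

expect_tables_equal <- function(a, b, tol = 1e-12) {
  expect_equal(dim(a), dim(b))
  expect_equal(rownames(a), rownames(b))
  expect_lt(max(abs(a - b)), tol + 1e-300)
}
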