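#' Align reads to hairpins by exhaustive ungapped scan
#'
#' Every read is compared against every hairpin at every offset on the
#' forward strand (the library protocol is stranded), counting Hamming
#' mismatches; no indels are considered. Placements exceeding
#' `max_mismatches` are dropped, and each read keeps only the placements at
#' its minimal observed mismatch count. Symbols outside {A,C,G,T} (after
#' U/T unification) never match, so they behave as mismatches at those
#' positions.
#'
#' @param reads A `read_set`, or a character vector of read sequences.
#' @param ref A [hairpin_reference()].
#' @param max_mismatches Mismatch cap (default 2).
#' @return A tibble with one row per kept placement: `read_id`, `read`,
#'   (index), `hairpin_id`, `start` (1-based), `width` (read length),
#'   `mismatches`. Reads with no acceptable placement contribute no rows.
#' @export
align_reads <- function(reads, ref, max_mismatches = 2L) {
  stopifnot(inherits(ref, "hairpin_reference"))
  if (inherits(reads, "read_set")) {
    seqs <- reads$sequence
    ids <- reads$read_id
  } else {
    seqs <- norm_seq(as.character(reads))
    ids <- if (is.null(names(reads))) as.character(seq_along(seqs)) else names(reads)
  }
  if (length(seqs) == 0L)
    return(tibble(read_id = character(0), read = integer(0),
                  hairpin_id = character(0), start = integer(0),
                  width = integer(0), mismatches = integer(0)))
  hits <- cpp_align_reads(seqs, unname(ref$sequences), as.integer(max_mismatches))
  tibble(read_id = ids[hits$read],
         read = hits$read,
         hairpin_id = names(ref$sequences)[hits$hairpin],
         start = hits$start,
         width = nchar(seqs)[hits$read],
         mismatches = hits$mismatches)
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one sequence.
#'
#' @param read A single nucleotide string.
#' @inheritParams align_reads
#' @return A tibble of minimal-mismatch placements (possibly zero rows).
#' @export
align_read <- function(read, ref, max_mismatches = 2L) {
  stopifnot(length(read) == 1L)
  align_reads(setNames(read, "read"), ref, max_mismatches)
}

#' Assign alignments to annotated mature arms
#'
#' A placement is attributed to a mature arm when its 5' end falls within
#' `window5` nt of the arm's annotated 5' end and the read overlaps the arm
#' by at least `min_overlap` nt. Placements satisfying neither condition
#' for any arm are hairpin-only and get `NA`. When two arms qualify the
#' one with the larger overlap wins, ties broken lexicographically by
#' mature id, so the result does not depend on annotation order.
#'
#' @param alignments A tibble as returned by [align_reads()].
#' @param ref A [hairpin_reference()].
#' @param window5 Allowed distance between read start and mature 5' end, nt.
#' @param min_overlap Minimum read/arm overlap, nt.
#' @return `alignments` with added columns `mature_id` (or `NA`),
#'   `offset5`, `offset3` (signed end shifts relative to the annotated arm;
#'   `NA` for unassigned placements).
#' @export
assign_to_mature <- function(alignments, ref, window5 = 3L, min_overlap = 16L) {
  stopifnot(inherits(ref, "hairpin_reference"))
  mat <- ref$matures
  aln <- as_tibble(alignments)
  aln$.row <- seq_len(nrow(aln))
  cand <- dplyr::inner_join(aln, mat, by = "hairpin_id",
                            suffix = c("", ".mat"),
                            relationship = "many-to-many")
  if (nrow(cand)) {
    aln_end <- cand$start + cand$width - 1L
    overlap <- pmin(aln_end, cand$end) - pmax(cand$start, cand$start.mat) + 1L
    ok <- abs(cand$start - cand$start.mat) <= window5 & overlap >= min_overlap
    cand <- cand[ok, , drop = FALSE]
    overlap <- overlap[ok]
    cand <- cand[order(cand$.row, -overlap, cand$mature_id), , drop = FALSE]
    cand <- cand[!duplicated(cand$.row), , drop = FALSE]
  }
  idx <- match(aln$.row, cand$.row)
  aln$mature_id <- cand$mature_id[idx]
  aln$offset5 <- aln$start - cand$start.mat[idx]
  aln$offset3 <- (aln$start + aln$width - 1L) - cand$end[idx]
  aln$.row <- NULL
  aln
}
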