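#' Hairpin reference with mature-arm annotations
#'
#' Container for the alignment target of the pipeline: miRNA precursor
#' (hairpin) sequences together with the 1-based inclusive coordinates of
#' their annotated mature arms, in the style of a miRBase release. U and T
#' are treated as equivalent; sequences are stored in the DNA alphabet.
#'
#' @param sequences Named character vector of hairpin sequences (names are
#'   hairpin ids). RNA (U) or DNA (T) alphabet.
#' @param matures Data frame with columns `hairpin_id`, `mature_id`,
#'   `start`, `end` (1-based inclusive positions on the hairpin).
#'
#' @return An object of class `hairpin_reference`: a list with elements
#'   `sequences` (named character, DNA alphabet) and `matures` (tibble).
#' @export
hairpin_reference <- function(sequences, matures) {
  if (length(sequences) == 0L) stop_fmt("reference must contain at least one hairpin")
  if (is.null(names(sequences)) || anyNA(names(sequences)) || any(names(sequences) == ""))
    stop_fmt("every hairpin sequence must be named")
  if (anyDuplicated(names(sequences)))
    stop_fmt("duplicated hairpin ids: %s",
             paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  sequences <- vapply(sequences, norm_seq, character(1))
  if (any(nchar(sequences) == 0L)) stop_fmt("hairpin sequences must be non-empty")
  bad <- grepl("[^ACGT]", sequences)
  if (any(bad))
    stop_fmt("hairpin %s contains symbols outside {A,C,G,U,T}",
             names(sequences)[bad][1])

  matures <- as_tibble(matures)
  need <- c("hairpin_id", "mature_id", "start", "end")
  if (!all(need %in% names(matures)))
    stop_fmt("mature annotation must have columns %s", paste(need, collapse = ", "))
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  unknown <- setdiff(matures$hairpin_id, names(sequences))
  if (length(unknown))
    stop_fmt("mature annotation references unknown hairpin id '%s'", unknown[1])
  if (anyDuplicated(matures$mature_id))
    stop_fmt("duplicated mature ids: %s",
             paste(unique(matures$mature_id[duplicated(matures$mature_id)]), collapse = ", "))
  hp_len <- nchar(sequences)[matures$hairpin_id]
  ok <- matures$start >= 1L & matures$start <= matures$end & matures$end <= hp_len
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop_fmt("mature '%s' has coordinates (%d, %d) outside hairpin '%s' (length %d)",
             matures$mature_id[i], matures$start[i], matures$end[i],
             matures$hairpin_id[i], hp_len[i])
  }
  structure(list(sequences = sequences, matures = matures[need]),
            class = "hairpin_reference")
}

#' @export
print.hairpin_reference <- function(x, ...) {
  cat(sprintf("<hairpin_reference> %d hairpins, %d mature arms\n",
              length(x$sequences), nrow(x$matures)))
  invisible(x)
}

#' Extract annotated mature sequences from a reference
#'
#' @param ref A [hairpin_reference()].
#' @return Named character vector of mature sequences (DNA alphabet).
#' @export
mature_sequences <- function(ref) {
  stopifnot(inherits(ref, "hairpin_reference"))
  setNames(substr(ref$sequences[ref$matures$hairpin_id],
                  ref$matures$start, ref$matures$end),
           ref$matures$mature_id)
}

#' Read a hairpin reference from FASTA plus a mature annotation table
#'
#' The annotation is a tab-separated table with columns `hairpin_id`,
#' `mature_id`, `start`, `end` (1-based inclusive, miRBase convention).
#'
#' @param fasta_path Path to the hairpin FASTA file (U or T alphabet).
#' @param annotation_path Path to the TSV mature annotation.
#' @return A [hairpin_reference()].
#' @export
read_hairpin_reference <- function(fasta_path, annotation_path) {
  seqs <- tryCatch(Biostrings::readBStringSet(fasta_path),
                   error = function(e) stop_fmt("malformed FASTA '%s': %s",
                                                fasta_path, conditionMessage(e)))
  sequences <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  ann <- read.delim(annotation_path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  hairpin_reference(sequences, ann)
}

#' Write a hairpin reference to FASTA plus a mature annotation table
#'
#' @param ref A [hairpin_reference()].
#' @param fasta_path,annotation_path Output paths.
#' @return `ref`, invisibly.
#' @export
write_hairpin_reference <- function(ref, fasta_path, annotation_path) {
  stopifnot(inherits(ref, "hairpin_reference"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(ref$sequences), fasta_path)
  write.table(ref$matures, annotation_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(ref)
}
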