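#' Construct a read set
#'
#' A read set is a tibble of reads tagged with the compartment it was
#' sequenced from (`cell` or `EV`) and a free-text condition label (for
#' example `"non-transfected"` or `"transfected"`). Qualities are not
#' stored: the pipeline performs no quality filtering.
#'
#' @param read_id Character vector of read identifiers.
#' @param sequence Character vector of read sequences (U or T alphabet).
#' @param library_label `"cell"` or `"EV"`.
#' @param condition_label Free-text condition tag.
#' @return A tibble of class `read_set` with columns `read_id`, `sequence`
#'   and attributes `library_label`, `condition_label`.
#' @export
read_set <- function(read_id, sequence, library_label,
                     condition_label = NA_character_) {
  library_label <- match.arg(library_label, c("cell", "EV"))
  sequence <- norm_seq(as.character(sequence))
  if (any(nchar(sequence) == 0L)) stop_fmt("read sequences must be non-empty")
  out <- tibble(read_id = as.character(read_id), sequence = sequence)
  attr(out, "library_label") <- library_label
  attr(out, "condition_label") <- condition_label
  class(out) <- c("read_set", class(out))
  out
}

#' Read a 4-line-record FASTQ file into a read set
#'
#' Quality strings are parsed and discarded: the pipeline's filtering is by
#' length only. A file whose line count is not a multiple of four is
#' reported as a truncated record with its record index.
#'
#' @param path FASTQ path.
#' @param library_label,condition_label See [read_set()].
#' @return A `read_set` (possibly empty).
#' @export
read_fastq <- function(path, library_label, condition_label = NA_character_) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4L != 0L)
    stop_fmt("truncated FASTQ record %d in '%s'", n %/% 4L + 1L, path)
  if (n == 0L)
    return(read_set(character(0), character(0), library_label, condition_label))
  headers <- lines[seq(1L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  bad <- !startsWith(headers, "@")
  if (any(bad)) stop_fmt("malformed FASTQ record %d in '%s': header does not start with '@'",
                         which(bad)[1], path)
  bad <- !startsWith(plus, "+")
  if (any(bad)) stop_fmt("malformed FASTQ record %d in '%s': separator line missing",
                         which(bad)[1], path)
  ids <- sub("\\s.*$", "", substring(headers, 2L))
  read_set(ids, lines[seq(2L, n, by = 4L)], library_label, condition_label)
}

#' Write a read set as FASTQ
#'
#' Emits a constant maximal quality (`I`, Phred+33) for every base, since
#' qualities carry no information in this pipeline.
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return `reads`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  qual <- strrep("I", nchar(reads$sequence))
  writeLines(as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                             "+", qual)), path)
  invisible(reads)
}

#' Adapter-trimming policy
#'
#' Trimming removes, from each read, the leftmost suffix that matches a
#' prefix of the 3' adapter with at most `max_adapter_mismatches` Hamming
#' mismatches over an overlap of at least `min_overlap` nt (no indels).
#' Trimmed reads shorter than `min_read_length` are discarded; the default
#' of 16 nt keeps reads of more than 15 bp. The default adapter is the
#' Illumina v1.5 small-RNA 3' adapter.
#'
#' @param adapter Adapter sequence (5' end is what follows the insert).
#' @param min_overlap Minimum read/adapter overlap, nt.
#' @param max_adapter_mismatches Maximum Hamming mismatches in the overlap.
#' @param min_read_length Minimum trimmed length kept, nt.
#' @param keep_untrimmed Keep reads in which no adapter is found (subject to
#'   the length filter)? The alternative discards them.
#' @return A list of class `trim_policy`.
#' @export
trim_policy <- function(adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                        min_overlap = 6L, max_adapter_mismatches = 1L,
                        min_read_length = 16L, keep_untrimmed = TRUE) {
  adapter <- norm_seq(adapter)
  min_overlap <- as.integer(min_overlap)
  min_read_length <- as.integer(min_read_length)
  if (min_overlap < 1L) stop_fmt("min_overlap must be >= 1")
  if (min_read_length < 1L) stop_fmt("min_read_length must be >= 1")
  if (nchar(adapter) < min_overlap)
    stop_fmt("adapter (%d nt) is shorter than min_overlap (%d nt)",
             nchar(adapter), min_overlap)
  structure(list(adapter = adapter, min_overlap = min_overlap,
                 max_adapter_mismatches = as.integer(max_adapter_mismatches),
                 min_read_length = min_read_length,
                 keep_untrimmed = isTRUE(keep_untrimmed)),
            class = "trim_policy")
}

#' Trim 3' adapters and filter reads by length
#'
#' @param reads A `read_set`.
#' @param policy A [trim_policy()].
#' @return The trimmed `read_set`, with a `trim_summary` attribute (a
#'   one-row tibble counting input, adapter-trimmed, untrimmed-kept,
#'   untrimmed-discarded, and too-short reads).
#' @export
trim_adapters <- function(reads, policy = trim_policy()) {
  stopifnot(inherits(reads, "read_set"), inherits(policy, "trim_policy"))
  n <- nrow(reads)
  if (n == 0L) {
    attr(reads, "trim_summary") <- tibble(
      n_input = 0L, n_trimmed = 0L, n_untrimmed_kept = 0L,
      n_untrimmed_discarded = 0L, n_too_short = 0L)
    return(reads)
  }
  pos <- cpp_find_adapter(reads$sequence, policy$adapter,
                          policy$min_overlap, policy$max_adapter_mismatches)
  has_adapter <- pos >= 0L
  trimmed_seq <- ifelse(has_adapter, substr(reads$sequence, 1L, pos),
                        reads$sequence)
  keep <- nchar(trimmed_seq) >= policy$min_read_length &
    (has_adapter | policy$keep_untrimmed)
  out <- reads[keep, , drop = FALSE]
  out$sequence <- trimmed_seq[keep]
  attr(out, "library_label") <- attr(reads, "library_label")
  attr(out, "condition_label") <- attr(reads, "condition_label")
  class(out) <- class(reads)
  attr(out, "trim_summary") <- tibble(
    n_input = n,
    n_trimmed = sum(has_adapter & keep),
    n_untrimmed_kept = sum(!has_adapter & keep),
    n_untrimmed_discarded = sum(!has_adapter & !keep & !policy$keep_untrimmed &
                                  nchar(trimmed_seq) >= policy$min_read_length),
    n_too_short = sum(!keep & nchar(trimmed_seq) < policy$min_read_length))
  out
}
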