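#' Per-library miRNA read count table
#'
#' @param counts Numeric matrix, rows = mature ids, columns = library
#'   labels. Counts may be fractional under multi-map splitting.
#' @return An object of class `count_table`: list with `counts` (matrix)
#'   and `total_mapped` (named column sums).
#' @export
count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_fmt("count matrix must have mature ids as rownames and library labels as colnames")
  if (any(counts < 0)) stop_fmt("counts must be non-negative")
  structure(list(counts = counts, total_mapped = colSums(counts)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d miRNAs x %d libraries; total mapped: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%.0f", names(x$total_mapped), x$total_mapped),
                    collapse = ", ")))
  invisible(x)
}

#' Quantify miRNA expression and isomiR structure across libraries
#'
#' Aligns each (trimmed) read set against the hairpin reference, assigns
#' minimal-mismatch placements to mature arms, and tabulates counts. Each
#' read carries total weight 1: when its minimal-mismatch placements hit
#' several mature arms the weight is split equally among them
#' (`multimap = "split"`), discarded (`"discard"`), or given to the
#' lexicographically first arm (`"first"`). IsomiR classes are keyed by
#' (5' offset, 3' offset, mismatch count); end offsets, not internal edit
#' positions, define an isomiR.
#'
#' @param readsets List of `read_set` objects (one per library). Library
#'   column names are taken from `names(readsets)` or built as
#'   `<library_label>_<condition_label>`.
#' @param ref A [hairpin_reference()].
#' @param max_mismatches Alignment mismatch cap.
#' @param window5,min_overlap Mature-assignment parameters, see
#'   [assign_to_mature()].
#' @param multimap Multi-mapping policy; see above.
#' @return A list with `counts` (a [count_table()] over all annotated
#'   matures) and `isomirs` (tibble: `library`, `mature_id`, `offset5`,
#'   `offset3`, `mismatches`, `count`, `fraction`).
#' @export
count_libraries <- function(readsets, ref, max_mismatches = 2L,
                            window5 = 3L, min_overlap = 16L,
                            multimap = c("split", "discard", "first")) {
  multimap <- match.arg(multimap)
  stopifnot(inherits(ref, "hairpin_reference"))
  labels <- names(readsets)
  if (is.null(labels)) {
    labels <- vapply(readsets, function(rs) {
      paste(stats::na.omit(c(attr(rs, "library_label"),
                             attr(rs, "condition_label"))), collapse = "_")
    }, character(1))
  }
  if (anyDuplicated(labels)) stop_fmt("library labels must be unique")

  mature_ids <- sort(ref$matures$mature_id)
  mat <- matrix(0, nrow = length(mature_ids), ncol = length(readsets),
                dimnames = list(mature_ids, labels))
  iso <- vector("list", length(readsets))

  for (j in seq_along(readsets)) {
    rs <- readsets[[j]]
    if (nrow(rs) == 0L) {
      warning(sprintf("library '%s' contains no reads", labels[j]),
              call. = FALSE)
      next
    }
    aln <- align_reads(rs, ref, max_mismatches)
    aln <- assign_to_mature(aln, ref, window5, min_overlap)
    aln <- aln[!is.na(aln$mature_id), , drop = FALSE]
    # one row per distinct (read, mature): several placements of the same
    # read on the same arm count once
    aln <- dplyr::distinct(aln, .data$read, .data$mature_id,
                           .keep_all = TRUE)
    if (nrow(aln) == 0L) next
    nm <- table(aln$read)
    k <- as.integer(nm[as.character(aln$read)])
    if (multimap == "discard") {
      aln <- aln[k == 1L, , drop = FALSE]
      aln$weight <- 1
    } else if (multimap == "first") {
      aln <- aln[order(aln$read, aln$mature_id), , drop = FALSE]
      aln <- aln[!duplicated(aln$read), , drop = FALSE]
      aln$weight <- 1
    } else {
      aln$weight <- 1 / k
    }
    if (nrow(aln) == 0L) next
    per_mature <- tapply(aln$weight, aln$mature_id, sum)
    mat[names(per_mature), j] <- as.numeric(per_mature)

    iso_j <- aln |>
      dplyr::group_by(.data$mature_id, .data$offset5, .data$offset3,
                      .data$mismatches) |>
      dplyr::summarise(count = sum(.data$weight), .groups = "drop") |>
      dplyr::group_by(.data$mature_id) |>
      dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
      dplyr::ungroup()
    iso_j$library <- labels[j]
    iso[[j]] <- iso_j
  }
  isomirs <- dplyr::bind_rows(iso)
  if (nrow(isomirs) == 0L)
    isomirs <- tibble(mature_id = character(0), offset5 = integer(0),
                      offset3 = integer(0), mismatches = integer(0),
                      count = numeric(0), fraction = numeric(0),
                      library = character(0))
  isomirs <- isomirs[, c("library", "mature_id", "offset5", "offset3",
                         "mismatches", "count", "fraction")]
  list(counts = count_table(mat), isomirs = isomirs)
}

#' Fraction of each mature's reads held by its most frequent isomiR
#'
#' @param isomirs IsomiR tibble from [count_libraries()].
#' @return Tibble `library`, `mature_id`, `dominant_fraction` plus the
#'   offsets and mismatch count of the dominant class.
#' @export
dominant_isomir <- function(isomirs) {
  isomirs |>
    dplyr::group_by(.data$library, .data$mature_id) |>
    dplyr::slice_max(.data$fraction, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("library", "mature_id", "offset5", "offset3",
                  "mismatches", dominant_fraction = "fraction")
}

#' Write / read a count table as TSV
#'
#' Rows are mature ids, columns are libraries; a final `TOTAL_MAPPED` row
#' carries the per-library denominators.
#'
#' @param x A [count_table()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_table"))
  df <- rbind(as.data.frame(x$counts), TOTAL_MAPPED = x$total_mapped)
  write.table(cbind(mature_id = rownames(df), df), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- df$mature_id
  df$mature_id <- NULL
  df <- df[setdiff(rownames(df), "TOTAL_MAPPED"), , drop = FALSE]
  count_table(as.matrix(df))
}
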