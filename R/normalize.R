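#' RPMM expression matrix
#'
#' Reads-per-million-mapped values per mature miRNA per library, together
#' with the per-library denominators (total mapped reads) and the ids of
#' any miRNAs excluded before renormalization. Within each library the
#' included values sum to one million.
#'
#' @param values Numeric matrix (mature id x library) of RPMM values.
#' @param denominators Named per-library totals the values were scaled by.
#' @param excluded Character vector of mature ids removed before
#'   renormalization (bookkeeping for downstream tables).
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, denominators, excluded = character(0)) {
  values <- as.matrix(values)
  if (any(values < 0)) stop_fmt("RPMM values must be non-negative")
  structure(list(values = values,
                 denominators = denominators,
                 excluded = excluded),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d miRNAs x %d libraries (RPMM)%s\n",
              nrow(x$values), ncol(x$values),
              if (length(x$excluded))
                sprintf("; excluded: %s", paste(x$excluded, collapse = ", "))
              else ""))
  invisible(x)
}

#' Normalize counts to reads per million mapped (RPMM)
#'
#' `value[i, lib] = count[i, lib] / total_mapped[lib] * 1e6`, so that
#' expression levels are directly comparable between libraries of
#' different depth.
#'
#' @param counts A [count_table()].
#' @return An [expression_matrix()].
#' @export
rpmm <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  zero <- counts$total_mapped <= 0
  if (any(zero))
    stop_fmt("library '%s' has zero mapped reads", names(which(zero))[1])
  expression_matrix(sweep(counts$counts, 2L, counts$total_mapped, "/") * 1e6,
                    counts$total_mapped)
}

#' Exclude miRNAs and renormalize the remainder to RPMM
#'
#' Used when an overexpressed miRNA (e.g. a transfected spike) dominates
#' the read pool: its rows are dropped and every remaining value is
#' rescaled per library so included values again sum to one million.
#' Pairwise ratios among the remaining miRNAs are unchanged, and the
#' result equals a de novo RPMM computed on counts without the excluded
#' rows.
#'
#' @param expr An [expression_matrix()].
#' @param exclude Character vector of mature ids to remove.
#' @return An [expression_matrix()] with the exclusion recorded.
#' @export
exclude_and_renormalize <- function(expr, exclude) {
  stopifnot(inherits(expr, "expression_matrix"))
  missing_ids <- setdiff(exclude, rownames(expr$values))
  if (length(missing_ids))
    stop_fmt("cannot exclude unknown mature id '%s'", missing_ids[1])
  keep <- setdiff(rownames(expr$values), exclude)
  vals <- expr$values[keep, , drop = FALSE]
  remaining <- colSums(vals)
  if (any(remaining <= 0))
    stop_fmt("excluding %s leaves library '%s' with no expressed miRNAs",
             paste(exclude, collapse = ", "), names(which(remaining <= 0))[1])
  vals <- sweep(vals, 2L, remaining, "/") * 1e6
  expression_matrix(vals, expr$denominators,
                    excluded = union(expr$excluded, exclude))
}

#' Library pairing for the cells/EVs study design
#'
#' @param ... Named arguments, one per condition, each a character vector
#'   with elements `cell` and `ev` naming the corresponding libraries.
#' @return A named list of class `library_pairing`.
#' @export
library_pairing <- function(...) {
  pairing <- list(...)
  if (length(pairing) == 0L || is.null(names(pairing)) ||
      any(names(pairing) == ""))
    stop_fmt("each condition must be named")
  for (cond in names(pairing)) {
    p <- pairing[[cond]]
    if (!all(c("cell", "ev") %in% names(p)))
      stop_fmt("condition '%s' must name a 'cell' and an 'ev' library", cond)
  }
  structure(pairing, class = "library_pairing")
}

#' Assign one read to the missing cell library of an EV-detected miRNA
#'
#' A miRNA detected in every EV library but in all-but-one of the cell
#' libraries is given one read in that remaining cell library, so an
#' EV:cell ratio can be computed for it. The pseudocount is applied on the
#' count scale, before normalization, and only ever converts a 0 to a 1;
#' the rule is idempotent. The symmetric rule (filling a single EV-side
#' zero) exists but is off by default.
#'
#' @param counts A [count_table()].
#' @param pairing A [library_pairing()] covering the libraries involved.
#' @param ev_side Also apply the mirrored EV-side rule?
#' @return A [count_table()] with pseudocounts applied.
#' @export
apply_pseudocount_rule <- function(counts, pairing, ev_side = FALSE) {
  stopifnot(inherits(counts, "count_table"),
            inherits(pairing, "library_pairing"))
  cell_libs <- vapply(pairing, `[[`, character(1), "cell")
  ev_libs <- vapply(pairing, `[[`, character(1), "ev")
  missing_libs <- setdiff(c(cell_libs, ev_libs), colnames(counts$counts))
  if (length(missing_libs))
    stop_fmt("pairing references unknown library '%s'", missing_libs[1])
  mat <- counts$counts
  fill_one_zero <- function(mat, must_libs, fill_libs) {
    detected_all <- rowSums(mat[, must_libs, drop = FALSE] > 0) ==
      length(must_libs)
    zeros <- mat[, fill_libs, drop = FALSE] == 0
    target <- detected_all & rowSums(zeros) == 1L
    for (lib in fill_libs)
      mat[target & zeros[, lib], lib] <- 1
    mat
  }
  mat <- fill_one_zero(mat, ev_libs, cell_libs)
  if (ev_side) mat <- fill_one_zero(mat, cell_libs, ev_libs)
  count_table(mat)
}

#' Write an expression matrix as TSV
#'
#' Header comment lines carry the per-library denominators and any
#' excluded mature ids.
#'
#' @param expr An [expression_matrix()].
#' @param path Output path.
#' @return `expr`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  stopifnot(inherits(expr, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# denominators: %s",
                       paste(sprintf("%s=%s", names(expr$denominators),
                                     format(expr$denominators, trim = TRUE)),
                             collapse = "\t")),
               sprintf("# excluded: %s",
                       paste(expr$excluded, collapse = "\t"))), con)
  write.table(cbind(mature_id = rownames(expr$values),
                    as.data.frame(expr$values)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}
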