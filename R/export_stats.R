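#' log2 EV:cell export ratio
#'
#' The export statistic: base-2 logarithm of a miRNA's EV expression over
#' its cellular expression (both RPMM). Positive values mark preferential
#' export, negative values retention. Nonpositive inputs yield `NA`, the
#' undefined-value marker; zeros are expected to have been handled by the
#' pseudocount rule.
#'
#' @param cell_rpmm,ev_rpmm Numeric vectors of RPMM values.
#' @return Numeric vector of log2(EV/cell) ratios (`NA` where undefined).
#' @export
log2_ev_cell <- function(cell_rpmm, ev_rpmm) {
  out <- rep(NA_real_, length(ev_rpmm))
  ok <- !is.na(cell_rpmm) & !is.na(ev_rpmm) & cell_rpmm > 0 & ev_rpmm > 0
  out[ok] <- log2(ev_rpmm[ok] / cell_rpmm[ok])
  out
}

#' Build the per-condition miRNA export table
#'
#' For every mature miRNA and condition, tabulates cell and EV RPMM, raw
#' read counts, the log2(EV/cell) ratio, an expression flag (raw reads
#' above `read_threshold` in at least one compartment, strict inequality)
#' and a class: `released` (ratio above +1), `retained` (below -1),
#' `similar` (within the closed band [-1, +1]) for expressed co-detected
#' miRNAs, `undetected` otherwise.
#'
#' @param expr An [expression_matrix()].
#' @param counts The [count_table()] the matrix was normalized from (raw
#'   reads drive the expression flag). Pass `NULL` to flag from RPMM
#'   instead (all miRNAs expressed when `read_threshold = 0`).
#' @param pairing A [library_pairing()].
#' @param read_threshold Raw-read expression threshold (default 1000,
#'   "more than" semantics).
#' @return A tibble of class `export_table`: `mature_id`, `condition`,
#'   `cell_rpmm`, `ev_rpmm`, `cell_reads`, `ev_reads`, `log2_ratio`,
#'   `expressed`, `class`, `excluded` (was the miRNA excluded during
#'   renormalization?).
#' @export
build_export_table <- function(expr, counts, pairing, read_threshold = 1000) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(pairing, "library_pairing"))
  ids <- rownames(expr$values)
  rows <- lapply(names(pairing), function(cond) {
    p <- pairing[[cond]]
    cell <- expr$values[, p[["cell"]]]
    ev <- expr$values[, p[["ev"]]]
    if (!is.null(counts)) {
      cr <- counts$counts[ids, p[["cell"]]]
      er <- counts$counts[ids, p[["ev"]]]
    } else {
      cr <- cell
      er <- ev
    }
    tibble(mature_id = ids, condition = cond,
           cell_rpmm = unname(cell), ev_rpmm = unname(ev),
           cell_reads = unname(cr), ev_reads = unname(er),
           log2_ratio = log2_ev_cell(cell, ev),
           expressed = pmax(cr, er) > read_threshold)
  })
  out <- dplyr::bind_rows(rows)
  out$class <- dplyr::case_when(
    is.na(out$log2_ratio) | !out$expressed ~ "undetected",
    out$log2_ratio > 1 ~ "released",
    out$log2_ratio < -1 ~ "retained",
    TRUE ~ "similar")
  out$excluded <- out$mature_id %in% expr$excluded
  class(out) <- c("export_table", class(out))
  out
}

#' Ranked released / retained miRNA lists
#'
#' Expressed, co-detected miRNAs ranked by descending (released) or
#' ascending (retained) log2(EV/cell); ties broken lexicographically by
#' mature id for determinism. The two lists are disjoint and exclude the
#' `similar` class.
#'
#' @param table An `export_table`.
#' @param condition Condition to rank within (default: first present).
#' @return List with tibbles `released` and `retained`, each carrying a
#'   `rank` column.
#' @export
released_retained <- function(table, condition = NULL) {
  if (is.null(condition)) condition <- table$condition[1]
  tab <- table[table$condition == condition, , drop = FALSE]
  rel <- tab[tab$class == "released", , drop = FALSE]
  rel <- rel[order(-rel$log2_ratio, rel$mature_id), , drop = FALSE]
  rel$rank <- seq_len(nrow(rel))
  ret <- tab[tab$class == "retained", , drop = FALSE]
  ret <- ret[order(ret$log2_ratio, ret$mature_id), , drop = FALSE]
  ret$rank <- seq_len(nrow(ret))
  list(released = as_tibble(rel), retained = as_tibble(ret))
}

sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  mean((x - m)^3) / s2^1.5
}

#' Summarize the distribution of log2(EV/cell) ratios
#'
#' Histogram of the export ratios of co-detected miRNAs, a normal fitted
#' by moments for visual comparison, the sample skewness (positive when
#' the distribution is shifted toward export), and the fraction of
#' co-detected miRNAs with similar representation in cells and EVs.
#'
#' @param table An `export_table` (one condition is selected).
#' @param condition Condition to summarize (default: first present).
#' @param bin_width Histogram bin width in log2 units.
#' @param similar_band `"open"` counts ratios strictly between -1 and +1
#'   (the reported-fraction convention); `"closed"` includes the
#'   endpoints (the classification convention).
#' @return A list of class `distribution_summary`: `breaks`, `counts`,
#'   `fitted_normal` (mean, sd), `skewness`, `fraction_similar`, `n`.
#' @export
distribution_summary <- function(table, condition = NULL, bin_width = 0.5,
                                 similar_band = c("open", "closed")) {
  similar_band <- match.arg(similar_band)
  if (is.null(condition)) condition <- table$condition[1]
  x <- table$log2_ratio[table$condition == condition]
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    stop_fmt("need at least 3 co-detected miRNAs, got %d", length(x))
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  similar <- if (similar_band == "open") x > -1 & x < 1 else x >= -1 & x <= 1
  structure(list(breaks = h$breaks, counts = h$counts,
                 fitted_normal = c(mean = mean(x), sd = sd(x)),
                 skewness = sample_skewness(x),
                 fraction_similar = mean(similar),
                 n = length(x)),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(paste0("<distribution_summary> n=%d co-detected miRNAs; ",
                     "mean=%.2f sd=%.2f skewness=%.2f; ",
                     "%.1f%% with log2(EV/cell) in the similar band\n"),
              x$n, x$fitted_normal[["mean"]], x$fitted_normal[["sd"]],
              x$skewness, 100 * x$fraction_similar))
  invisible(x)
}

#' Coefficient of determination between two expression profiles
#'
#' Pearson R^2 over shared miRNAs passing a read threshold, on the log
#' scale (log2 of value + 1, the default) or raw scale. Inputs may be
#' named numeric vectors, single-library slices of an
#' [expression_matrix()] (`expr$values[, lib]`), or `export_table`
#' log2-ratio vectors via [export_ratio_vector()].
#'
#' @param a,b Named numeric vectors over miRNA ids.
#' @param scale `"log"` or `"raw"`.
#' @param min_value Keep only miRNAs with value above this in at least one
#'   profile (on the raw scale); default 0 keeps all co-detected.
#' @return A list of class `correlation_report`: `r_squared`, `n`,
#'   `scale`, `min_value`.
#' @export
correlation_report <- function(a, b, scale = c("log", "raw"), min_value = 0) {
  scale <- match.arg(scale)
  if (is.null(names(a)) || is.null(names(b)))
    stop_fmt("profiles must be named by miRNA id")
  shared <- intersect(names(a), names(b))
  a <- a[shared]; b <- b[shared]
  ok <- is.finite(a) & is.finite(b) & (pmax(a, b) > min_value | min_value <= 0)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3L)
    stop_fmt("need at least 3 shared miRNAs, got %d", length(a))
  if (scale == "log") {
    a <- log2(a + 1); b <- log2(b + 1)
  }
  structure(list(r_squared = unname(cor(a, b)^2), n = length(a),
                 scale = scale, min_value = min_value),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> R^2 = %.3f over %d miRNAs (%s scale)\n",
              x$r_squared, x$n, x$scale))
  invisible(x)
}

#' Extract a named log2-ratio vector from an export table
#'
#' @param table An `export_table`.
#' @param condition Condition to extract.
#' @param expressed_only Keep only miRNAs passing the expression flag?
#' @return Named numeric vector of log2(EV/cell) ratios.
#' @export
export_ratio_vector <- function(table, condition = NULL,
                                expressed_only = TRUE) {
  if (is.null(condition)) condition <- table$condition[1]
  tab <- table[table$condition == condition, , drop = FALSE]
  if (expressed_only) tab <- tab[tab$expressed, , drop = FALSE]
  setNames(tab$log2_ratio, tab$mature_id)
}

#' Format an export table the way published released/retained tables print
#'
#' @param table An `export_table`.
#' @param digits Decimal places for the log2 ratio (1 matches the
#'   released-list display; 2 the retained-list display).
#' @return A tibble with RPMM values and the rounded ratio.
#' @export
format_export_table <- function(table, digits = 2) {
  tibble(mature_id = table$mature_id, condition = table$condition,
         cell_rpmm = round(table$cell_rpmm, 2),
         ev_rpmm = round(table$ev_rpmm, 2),
         log2_ev_cell = round(table$log2_ratio, digits))
}
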