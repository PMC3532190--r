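#' Per-dataset miRNA export measure
#'
#' Wraps one dataset's export scores for cross-dataset rank comparison.
#' For sequencing and microarray platforms the score is the EV:cell
#' expression ratio; for RT-qPCR arrays it is the delta-Ct, defined as
#' Ct(cells) - Ct(EV) so that larger always means more exported (a lower
#' Ct in EVs means higher EV abundance). A measured zero participates in
#' ranking; a miRNA absent from the platform is simply not listed (or is
#' flagged undetected) and appears blank downstream.
#'
#' @param dataset_id Dataset identifier.
#' @param platform `"sequencing"`, `"microarray"`, or `"qpcr_array"`.
#' @param scores Named numeric vector of export scores, or `NULL` to
#'   derive them from `cell_value`/`ev_value`.
#' @param mature_id,cell_value,ev_value Alternative tabular input: per
#'   miRNA expression in cells and EVs (Ct values for `qpcr_array`,
#'   intensities/reads otherwise).
#' @param detected Logical vector; defaults to finite score.
#' @return A tibble of class `dataset_measure` with columns `mature_id`,
#'   `score`, `detected` and attributes `dataset_id`, `platform`.
#' @export
dataset_measure <- function(dataset_id, platform, scores = NULL,
                            mature_id = NULL, cell_value = NULL,
                            ev_value = NULL, detected = NULL) {
  platform <- match.arg(platform, c("sequencing", "microarray", "qpcr_array"))
  if (is.null(scores)) {
    if (is.null(mature_id)) stop_fmt("provide scores or per-miRNA values")
    scores <- if (platform == "qpcr_array") {
      setNames(cell_value - ev_value, mature_id)  # delta Ct, cells - EV
    } else {
      setNames(ev_value / cell_value, mature_id)
    }
  }
  if (is.null(names(scores))) stop_fmt("scores must be named by miRNA id")
  if (is.null(detected)) detected <- is.finite(scores)
  out <- tibble(mature_id = names(scores), score = unname(scores),
                detected = detected)
  attr(out, "dataset_id") <- dataset_id
  attr(out, "platform") <- platform
  class(out) <- c("dataset_measure", class(out))
  out
}

#' Rank a dataset's miRNAs by export score
#'
#' Rank 1 is the most exported miRNA: highest EV:cell ratio, or highest
#' delta-Ct for qPCR arrays (equivalently, any strictly monotone transform
#' of the scores yields the same ranks). Ties get average (fractional)
#' ranks. Ranks cover the dataset's detected miRNAs only.
#'
#' @param measure A [dataset_measure()].
#' @return The measure with a `rank` column (`NA` where undetected).
#' @export
rank_dataset <- function(measure) {
  stopifnot(inherits(measure, "dataset_measure"))
  det <- measure$detected & is.finite(measure$score)
  if (sum(det) < 2L)
    stop_fmt("dataset '%s' has fewer than 2 detected miRNAs",
             attr(measure, "dataset_id"))
  measure$rank <- NA_real_
  measure$rank[det] <- rank(-measure$score[det], ties.method = "average")
  measure
}

#' Build a cross-dataset rank matrix
#'
#' Rows are the reference dataset's detected miRNAs sorted by reference
#' rank (most exported first). Each other dataset contributes the NATIVE
#' rank of those miRNAs — computed over that dataset's full detected set
#' before restriction to the reference rows — or a blank (`NA`) where the
#' miRNA was not detected or not assayed. A decile band per cell (1 = top
#' decile of that dataset's own ranking) supports heatmap display.
#'
#' @param reference A [dataset_measure()] serving as the row ordering.
#' @param others List of [dataset_measure()] objects.
#' @return A list of class `rank_matrix`: `ranks` (matrix miRNA x
#'   dataset), `bands` (decile index matrix), `n_detected` (per dataset),
#'   `reference_dataset`.
#' @export
build_rank_matrix <- function(reference, others) {
  all_meas <- c(list(reference), others)
  all_meas <- lapply(all_meas, function(m)
    if ("rank" %in% names(m)) m else rank_dataset(m))
  ids <- vapply(all_meas, attr, character(1), "dataset_id")
  if (anyDuplicated(ids)) stop_fmt("dataset ids must be unique")
  ref <- all_meas[[1]]
  ref_rows <- ref[!is.na(ref$rank), , drop = FALSE]
  ref_rows <- ref_rows[order(ref_rows$rank), , drop = FALSE]
  n_det <- vapply(all_meas, function(m) sum(!is.na(m$rank)), numeric(1))
  names(n_det) <- ids
  ranks <- vapply(all_meas, function(m)
    m$rank[match(ref_rows$mature_id, m$mature_id)],
    numeric(nrow(ref_rows)))
  ranks <- matrix(ranks, nrow = nrow(ref_rows),
                  dimnames = list(ref_rows$mature_id, ids))
  bands <- ceiling(sweep(ranks, 2L, n_det, "/") * 10)
  bands[] <- pmin(pmax(bands, 1), 10)
  structure(list(ranks = ranks, bands = bands, n_detected = n_det,
                 reference_dataset = ids[1]),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d miRNAs (reference '%s') x %d datasets; %.0f%% blank\n",
              nrow(x$ranks), x$reference_dataset, ncol(x$ranks),
              100 * mean(is.na(x$ranks))))
  invisible(x)
}

#' Pairwise rank concordance between datasets
#'
#' Spearman rank correlation per dataset pair over co-detected miRNAs in
#' the rank matrix, plus the overlap of the datasets' native top-`k` most
#' exported miRNAs. Pairs sharing fewer than 3 miRNAs are marked
#' not-computable (`NA`).
#'
#' @param matrix A [build_rank_matrix()] result.
#' @param k Top-list size for the overlap count.
#' @return Tibble: `dataset_a`, `dataset_b`, `n_shared`, `spearman`,
#'   `top_k_overlap`, `computable`.
#' @export
concordance <- function(matrix, k = 6L) {
  stopifnot(inherits(matrix, "rank_matrix"))
  ids <- colnames(matrix$ranks)
  if (length(ids) < 2L) stop_fmt("need at least 2 datasets")
  pairs <- utils::combn(ids, 2L)
  rows <- apply(pairs, 2L, function(p) {
    ra <- matrix$ranks[, p[1]]; rb <- matrix$ranks[, p[2]]
    ok <- !is.na(ra) & !is.na(rb)
    n <- sum(ok)
    sp <- if (n >= 3L) unname(cor(ra[ok], rb[ok], method = "spearman")) else NA_real_
    top_a <- rownames(matrix$ranks)[!is.na(ra) & ra <= k]
    top_b <- rownames(matrix$ranks)[!is.na(rb) & rb <= k]
    tibble(dataset_a = p[1], dataset_b = p[2], n_shared = n,
           spearman = sp, top_k_overlap = length(intersect(top_a, top_b)),
           computable = n >= 3L)
  })
  dplyr::bind_rows(rows)
}

#' Read / write dataset measures and rank matrices as TSV
#'
#' The dataset TSV has a `# dataset:` / `# platform:` header followed by
#' columns `mature_id`, `cell_value`, `ev_value`.
#'
#' @param path File path.
#' @return For the reader, a [dataset_measure()].
#' @export
read_dataset_measure <- function(path) {
  hdr <- readLines(path, n = 2L)
  ds <- sub("^#\\s*dataset:\\s*", "", hdr[1])
  pf <- sub("^#\\s*platform:\\s*", "", hdr[2])
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  dataset_measure(ds, pf, mature_id = df$mature_id,
                  cell_value = df$cell_value, ev_value = df$ev_value)
}

#' @rdname read_dataset_measure
#' @param measure A [dataset_measure()] built from cell/EV values.
#' @param cell_value,ev_value Per-miRNA values to serialize alongside.
#' @export
write_dataset_measure <- function(measure, path, cell_value, ev_value) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# dataset: %s", attr(measure, "dataset_id")),
               sprintf("# platform: %s", attr(measure, "platform"))), con)
  write.table(data.frame(mature_id = measure$mature_id,
                         cell_value = cell_value, ev_value = ev_value),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(measure)
}

#' @rdname read_dataset_measure
#' @param matrix A `rank_matrix`.
#' @export
write_rank_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "rank_matrix"))
  df <- cbind(mature_id = rownames(matrix$ranks),
              as.data.frame(matrix$ranks))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(matrix)
}
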