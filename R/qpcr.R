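#' RT-qPCR Ct table
#'
#' Long-format threshold-cycle measurements: one row per (sample, miRNA,
#' replicate). Relative quantification normalizes every miRNA to a
#' reference miRNA measured in the same sample (the pipeline's default
#' study used miR-26a, chosen for high, compartment-balanced expression).
#' Undetermined wells are encoded as missing rows, never as Ct 40.
#'
#' @param sample,mirna Character vectors.
#' @param replicate Integer replicate index.
#' @param ct Numeric Ct values (PCR cycles, typically 10-40).
#' @param reference_mirna The normalizer miRNA; must be measured in every
#'   sample.
#' @return A tibble of class `ct_table` with attribute `reference_mirna`.
#' @export
ct_table <- function(sample, mirna, replicate, ct, reference_mirna) {
  out <- tibble(sample = as.character(sample), mirna = as.character(mirna),
                replicate = as.integer(replicate), ct = as.numeric(ct))
  if (any(!is.finite(out$ct))) stop_fmt("Ct values must be finite")
  for (s in unique(out$sample)) {
    if (!reference_mirna %in% out$mirna[out$sample == s])
      stop_fmt("reference miRNA '%s' not measured in sample '%s'",
               reference_mirna, s)
  }
  attr(out, "reference_mirna") <- reference_mirna
  class(out) <- c("ct_table", class(out))
  out
}

#' Read a Ct table from CSV
#'
#' Expects columns `sample`, `mirna`, `replicate`, `ct`.
#'
#' @param path CSV path.
#' @param reference_mirna Normalizer miRNA id.
#' @return A [ct_table()].
#' @export
read_ct_table <- function(path, reference_mirna) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ct_table(df$sample, df$mirna, df$replicate, df$ct, reference_mirna)
}

mean_ct <- function(ct, sample, mirna) {
  x <- ct$ct[ct$sample == sample & ct$mirna == mirna]
  if (length(x) == 0L) return(NA_real_)
  mean(x)
}

#' Relative expression by the 2^-deltaCt method
#'
#' Replicate Cts are averaged (arithmetic mean on the Ct scale) first;
#' then `deltaCt = meanCt(miRNA) - meanCt(reference)` and the relative
#' expression is `efficiency^-deltaCt`. With the default amplification
#' efficiency of 2 (reactions optimized to double per cycle) this is the
#' standard 2^-deltaCt quantity. A miRNA not measured in the sample
#' returns `NA` (undetected); a missing reference is an error.
#'
#' @param ct A [ct_table()].
#' @param sample Sample label.
#' @param mirna miRNA id.
#' @param efficiency Amplification efficiency (default 2).
#' @return Dimensionless relative expression.
#' @export
relative_expression <- function(ct, sample, mirna, efficiency = 2) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference_mirna")
  ref_ct <- mean_ct(ct, sample, ref)
  if (is.na(ref_ct))
    stop_fmt("reference miRNA '%s' missing from sample '%s'", ref, sample)
  target_ct <- mean_ct(ct, sample, mirna)
  if (is.na(target_ct)) return(NA_real_)
  efficiency^-(target_ct - ref_ct)
}

#' Relative expression of every (sample, miRNA) pair
#'
#' @inheritParams relative_expression
#' @return Tibble: `sample`, `mirna`, `n_replicates`, `mean_ct`, `sd_ct`,
#'   `delta_ct`, `rel_expr`, plus `sd_rel_expr`, the standard deviation of
#'   the per-replicate `efficiency^-deltaCt` values (both spread measures
#'   are reported since either may be wanted for error bars).
#' @export
relative_expression_table <- function(ct, efficiency = 2) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference_mirna")
  refs <- ct |>
    dplyr::filter(.data$mirna == ref) |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(ref_ct = mean(.data$ct), .groups = "drop")
  ct |>
    dplyr::group_by(.data$sample, .data$mirna) |>
    dplyr::summarise(n_replicates = dplyr::n(), mean_ct = mean(.data$ct),
                     sd_ct = sd(.data$ct),
                     .sd_rel = sd(efficiency^-(.data$ct -
                                                 mean(.data$ct))),
                     .groups = "drop") |>
    dplyr::left_join(refs, by = "sample") |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$ref_ct,
                  rel_expr = efficiency^-(.data$delta_ct),
                  sd_rel_expr = .data$.sd_rel * .data$rel_expr) |>
    dplyr::select("sample", "mirna", "n_replicates", "mean_ct", "sd_ct",
                  "delta_ct", "rel_expr", "sd_rel_expr")
}

#' EV:cell expression ratio from qPCR
#'
#' Ratio of a miRNA's reference-normalized relative expression in the EV
#' sample over the cell sample; equals
#' `efficiency^(deltaCt_cell - deltaCt_EV)`, so on the log2 scale (with
#' efficiency 2) the ratio is exactly `deltaCt_cell - deltaCt_EV`.
#'
#' @inheritParams relative_expression
#' @param cell_sample,ev_sample Sample labels of the paired compartments.
#' @return Dimensionless EV:cell ratio (`NA` when the miRNA is undetected
#'   in either sample).
#' @export
qpcr_ev_cell_ratio <- function(ct, mirna, cell_sample, ev_sample,
                               efficiency = 2) {
  ev <- relative_expression(ct, ev_sample, mirna, efficiency)
  cell <- relative_expression(ct, cell_sample, mirna, efficiency)
  ev / cell
}
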