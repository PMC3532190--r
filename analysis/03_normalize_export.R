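#!/usr/bin/env Rscript
# Step 3: RPMM normalization with the pseudocount rule, exclusion of the
# overexpressed spike with renormalization, the log2(EV/cell) export
# tables, between-library correlations and the export-ratio distribution.
# Writes results/export/.

suppressPackageStartupMessages(library(mirexport))

out <- "results/export"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

counts <- read_count_table("results/quantify/counts.tsv")
pairing <- library_pairing(nt = c(cell = "cell_nt", ev = "ev_nt"),
                           tf = c(cell = "cell_tf", ev = "ev_tf"))

counts <- apply_pseudocount_rule(counts, pairing)
expr <- rpmm(counts)

# identify the spike as the miRNA holding the largest transfected share
spike_id <- rownames(expr$values)[which.max(expr$values[, "cell_tf"])]
message(sprintf("excluding overexpressed '%s' (%.0f%% of transfected cell reads) and renormalizing",
                spike_id, expr$values[spike_id, "cell_tf"] / 1e4))
renorm <- exclude_and_renormalize(expr, spike_id)
write_expression_matrix(renorm, file.path(out, "rpmm_renormalized.tsv"))

# transfected values join the non-transfected ones after renormalization;
# the export table uses renormalized RPMM for tf and plain RPMM for nt
tab_nt <- build_export_table(expr, counts,
                             library_pairing(nt = pairing$nt),
                             read_threshold = 20)
tab_tf <- build_export_table(renorm, counts,
                             library_pairing(tf = pairing$tf),
                             read_threshold = 20)
tab <- rbind(tab_nt, tab_tf)
write.table(format_export_table(tab), file.path(out, "export_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rr <- released_retained(tab_nt)
message(sprintf("most released: %s (log2 = %.1f); most retained: %s (log2 = %.2f)",
                rr$released$mature_id[1], rr$released$log2_ratio[1],
                rr$retained$mature_id[1], rr$retained$log2_ratio[1]))

# between-library correlations after exclusion-renormalization
cors <- list(
  cells_nt_vs_tf = correlation_report(expr$values[rownames(renorm$values), "cell_nt"],
                                      renorm$values[, "cell_tf"]),
  evs_nt_vs_tf = correlation_report(expr$values[rownames(renorm$values), "ev_nt"],
                                    renorm$values[, "ev_tf"]),
  cells_vs_evs_nt = correlation_report(expr$values[, "cell_nt"],
                                       expr$values[, "ev_nt"]))
for (nm in names(cors))
  message(sprintf("R^2 %s = %.3f (n = %d, log scale)", nm,
                  cors[[nm]]$r_squared, cors[[nm]]$n))

# ratio stability: log2 ratios before vs after overexpression
stab <- correlation_report(2^export_ratio_vector(tab_nt),
                           2^export_ratio_vector(tab_tf, "tf"))
message(sprintf("R^2 of EV:cell ratios across conditions = %.3f (n = %d)",
                stab$r_squared, stab$n))

d <- distribution_summary(tab_nt)
print(d)
hist_df <- data.frame(left = head(d$breaks, -1), right = d$breaks[-1],
                      count = d$counts)
write.table(hist_df, file.path(out, "log2_ratio_histogram.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  x <- tab_nt$log2_ratio[is.finite(tab_nt$log2_ratio)]
  p <- ggplot2::ggplot(data.frame(x = x), ggplot2::aes(x)) +
    ggplot2::geom_histogram(binwidth = 0.5, fill = "steelblue",
                            color = "white") +
    ggplot2::stat_function(
      fun = function(z) length(x) * 0.5 *
        stats::dnorm(z, d$fitted_normal[["mean"]], d$fitted_normal[["sd"]]),
      color = "grey30") +
    ggplot2::labs(x = "log2(EV/cell)", y = "miRNAs",
                  title = "Export-ratio distribution vs fitted normal")
  ggplot2::ggsave(file.path(out, "log2_ratio_distribution.png"), p,
                  width = 6, height = 4, dpi = 150)
}
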