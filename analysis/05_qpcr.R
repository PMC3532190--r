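#!/usr/bin/env Rscript
# Step 5: RT-qPCR confirmation in silico - simulate triplicate Ct values
# from the ground-truth abundances, quantify by 2^-deltaCt against a
# compartment-balanced reference miRNA, and compare EV:cell ratios with
# the sequencing-derived ones. Writes results/qpcr/.

suppressPackageStartupMessages(library(mirexport))

out <- "results/qpcr"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

gt <- read.delim("results/sim/ground_truth.tsv")
truth <- structure(list(
  cell_proportions = setNames(gt$cell_proportion, gt$mature_id),
  ev_proportions = setNames(gt$ev_proportion, gt$mature_id),
  e = setNames(gt$e, gt$mature_id)), class = "ground_truth")

# reference: high expression with EV:cell ratio near 1, the standard
# choice for a qPCR normalizer in this design
balanced <- abs(log2(truth$ev_proportions) - log2(truth$cell_proportions))
candidates <- names(truth$e)[rank(-pmin(truth$cell_proportions,
                                        truth$ev_proportions)) <= 20]
ref_id <- candidates[which.min(balanced[candidates])]
message(sprintf("reference miRNA: %s (log2 EV:cell = %.2f)",
                ref_id, (log2(truth$ev_proportions) -
                           log2(truth$cell_proportions))[ref_id]))

ct <- simulate_ct_table(truth, reference_mirna = ref_id, noise_sd = 0.2,
                        seed = 20120805)
rel <- relative_expression_table(ct)
write.table(rel, file.path(out, "relative_expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ids <- names(truth$e)
qratio <- vapply(ids, function(m)
  qpcr_ev_cell_ratio(ct, m, "cell", "EV"), numeric(1))
seq_ratio <- truth$ev_proportions / truth$cell_proportions
comp <- data.frame(mature_id = ids,
                   log2_qpcr = log2(qratio),
                   log2_sequencing = log2(seq_ratio))
write.table(comp, file.path(out, "qpcr_vs_sequencing.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ok <- is.finite(comp$log2_qpcr) & is.finite(comp$log2_sequencing)
r2 <- cor(comp$log2_qpcr[ok], comp$log2_sequencing[ok])^2
message(sprintf("R^2 between qPCR and sequencing log2 EV:cell ratios: %.3f (n = %d)",
                r2, sum(ok)))
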