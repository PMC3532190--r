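# mirexport

Quantifying selective microRNA export into extracellular vesicles (EVs)
from small-RNA sequencing.

Cells shed membrane vesicles — exosomes and shedding vesicles — that carry
miRNAs to other cells. If packaging were passive, the EV miRNA pool would
mirror the cellular pool. It does not: a reproducible subset of miRNAs
(miR-451 being the extreme case) is strongly enriched in EVs while others
are retained. `mirexport` implements the complete measurement pipeline for
this question, for researchers analysing paired cell/EV small-RNA
libraries or reanalysing published cell-vs-EV expression tables:

* **Read processing** — 3' adapter trimming (suffix/prefix Hamming scan),
  ">15 bp" length filtering, FASTQ/FASTA I/O.
* **Quantification** — exhaustive ungapped alignment to miRNA hairpins
  with ≤2 mismatches (Rcpp), assignment to annotated mature arms, equal
  splitting of multi-mappers, isomiR tabulation by 5'/3' end offsets.
* **Normalization** — reads per million mapped (RPMM); a pseudocount rule
  that assigns one read when a miRNA is EV-detected but missing from one
  cell library; exclusion–renormalization for overexpressed miRNAs.
* **Export statistics** — the per-miRNA export ratio

  log2(EV/cell) = log2(RPMM_EV / RPMM_cell),

  released/retained classification (±1 log2-unit band), ranked lists,
  ratio-distribution summaries (histogram, moment-fit normal, skewness),
  and between-library R².
* **RT-qPCR** — relative quantification by 2^−ΔCt normalized to a
  reference miRNA, and EV:cell ratios with the exact identity
  log2(ratio) = ΔCt_cell − ΔCt_EV.
* **Cross-dataset concordance** — per-dataset export ranking (ratios or
  ΔCt), a rank matrix that keeps each dataset's native ranks, Spearman
  concordance and top-k overlap.
* **Synthetic data** — a generator with full ground truth emulating the
  four-library cells/EVs × non-transfected/transfected design, including
  a 32%/44% overexpression spike, isomiR structure, sequencing error and
  adapters; every downstream test is anchored on it.

## Worked example

Published RPMM values for HEK293T cells and their EVs are bundled as a
worked example:

```r
library(mirexport)

vals <- hek293t_export_values()
nt <- subset(vals, condition == "non_transfected")

# recompute the export statistic from the RPMM pairs
round(log2_ev_cell(0.4, 3945.0), 1)       # mir-451:  13.3
round(log2_ev_cell(1342.24, 135.00), 2)   # mir-218: -3.31

# rank released and retained miRNAs
expr <- expression_matrix(
  cbind(cell = setNames(nt$cell_rpmm, nt$mature_id),
        ev   = setNames(nt$ev_rpmm,  nt$mature_id)),
  c(cell = 1e6, ev = 1e6))
tab <- build_export_table(expr, NULL,
                          library_pairing(nt = c(cell = "cell", ev = "ev")),
                          read_threshold = 0)
rr <- released_retained(tab)
rr$released$mature_id[1]   # "mir-451"  (most exported, log2 = 13.3)
rr$retained$mature_id[1]   # "mir-218"  (most retained, log2 = -3.31)
```

The overexpression spike in the transfected condition converts to pool
shares directly: 317,863 RPMM is 32% of cellular reads and 440,496 RPMM is
44% of EV reads.

A full simulated run lives in `analysis/` as numbered scripts:
`01_simulate_libraries.R` (four libraries with ground truth) →
`02_quantify.R` (trim, align, count; recovers the simulated counts with
r = 1.0000 and a dominant-isomiR share of 49% against a configured 50%) →
`03_normalize_export.R` (pseudocounts, spike exclusion, export tables,
R² between libraries) → `04_published_tables.R` (the example above) →
`05_qpcr.R` (2^−ΔCt vs sequencing ratios, R² = 0.985 on the default
seed) → `06_cross_dataset.R` (8-dataset rank matrix and concordance).
Each writes its tables under `results/`.

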