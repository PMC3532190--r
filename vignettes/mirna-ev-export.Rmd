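---
title: "Measuring selective miRNA export into extracellular vesicles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring selective miRNA export into extracellular vesicles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirexport)
```

## The question and the measurement

Cells release membrane-bound extracellular vesicles (EVs) — exosomes and
shedding vesicles — that carry microRNAs. If miRNAs were packaged passively,
an EV's miRNA pool would be a random sample of the cellular pool and, after
depth normalization, each miRNA would be equally represented in both
compartments. The measurement this package implements asks how far reality
departs from that null: small-RNA libraries are sequenced from cells and
from their EVs, each miRNA is quantified in both, and the export statistic

$$\log_2(\mathrm{EV}/\mathrm{cell}) \;=\; \log_2
  \frac{\mathrm{RPMM}_{\mathrm{EV}}}{\mathrm{RPMM}_{\mathrm{cell}}}$$

is computed per miRNA, where RPMM (reads per million mapped) is the read
count scaled by $10^6$ over the library's total miRNA-mapped reads.
Positive values mark preferentially *released* miRNAs, negative values
*retained* ones, and values within one unit of zero *similar*
representation. Because RPMM is a compositional (depth-free) measure, no
internal standard is needed — the property that makes digital counting
attractive for cell/EV comparisons, where no common reference transcript is
known.

## From reads to counts

Raw reads are 3' adapter-trimmed: the leftmost suffix of the read matching
a prefix of the adapter with at most `max_adapter_mismatches` Hamming
mismatches over at least `min_overlap` nt is removed (no indels — adapter
contamination in short reads is a substitution-error process). Reads
trimmed below `min_read_length = 16` nt are discarded, encoding the
">15 bp" rule as a strict inequality. Reads with no detectable adapter are
kept by default since discarding them is a protocol choice, not a
necessity; `trim_policy(keep_untrimmed = FALSE)` flips it.

Trimmed reads are aligned to a hairpin (precursor) reference by exhaustive
ungapped scan on the forward strand, keeping placements with at most 2
mismatches and then only those at each read's minimal observed mismatch
count. Ungapped matching with a mismatch cap is the convention for
~22 nt reads against ~80 nt hairpins; the library protocol is stranded, so
reverse-complement matching is off. The scan is exact by construction and
is verified in the test suite against an independent pure-R enumeration
oracle on every instance up to 30 hairpins.

A placement is attributed to an annotated mature arm when its 5' end lies
within ±3 nt of the arm's annotated 5' end and it overlaps the arm by at
least 16 nt. These two windows are exposed as parameters
(`assign_to_mature(window5 =, min_overlap =)`) because the assignment rule
of the original commercial pipeline is not documented anywhere; ±3 nt
covers the 5'-isomiR range actually observed while excluding loop- and
star-side placements. A read whose minimal-mismatch placements hit several
arms carries total weight 1 split equally among them (configurable to
`discard` or `first`), which preserves the conservation property that
column totals equal assigned read numbers exactly.

IsomiRs — end variants of a mature miRNA — are keyed by the signed 5' and
3' offsets relative to the annotated arm plus the mismatch count.
Positions of internal edits are deliberately not part of the key: isomiR
displays in this field distinguish molecules by their ends. The
`dominant_fraction` of a mature is the share of its reads held by its most
frequent class.

## Normalization: RPMM, pseudocounts, exclusion–renormalization

`rpmm()` is the plain scaling $c_{i\ell} \cdot 10^6 / \sum_i c_{i\ell}$.
Two refinements matter in this design:

* **Pseudocount rule.** A miRNA detected in every EV library but in all
  but one cell library has no defined ratio in that one condition purely
  because of sampling at low expression. Such a miRNA is assigned one
  read in the missing cell library — on the count scale, *before*
  normalization, so the single read flows through that library's own
  denominator. The rule is idempotent, only ever converts a 0 to a 1, and
  its mirrored EV-side variant exists but is off by default since only the
  cell-side rule is part of the original design.
* **Exclusion–renormalization.** When a transfected miRNA seizes a third
  or more of the read pool, every other miRNA's RPMM is compressed and
  libraries stop being comparable. `exclude_and_renormalize()` drops the
  overexpressed species and rescales each library so included values again
  sum to $10^6$. This is exactly a per-library multiplicative rescaling:
  pairwise ratios among remaining miRNAs are unchanged (tested to 1e-9
  relative), and the result equals de novo RPMM on spike-free counts
  (tested as a two-route equality). A spike holding the *same* pool share
  in both compartments cancels in the ratio, so export statistics are
  unchanged; unequal shares (as with a 32%/44% spike) shift all log2
  ratios by a common per-condition constant.

## Export tables, classification and summaries

`build_export_table()` applies the expression filter on **raw reads**
(more than 1000 in at least one compartment, strict), not RPMM, because a
count threshold is a statement about evidence, not concentration. The
*similar* band is the closed interval $[-1, +1]$ for classification;
`distribution_summary()` defaults to the open interval when reporting the
fraction of co-detected miRNAs with similar representation, matching the
convention of the reported fraction ("between −1 and +1"); both are
selectable. Ranked released/retained lists break ties lexicographically so
output is deterministic.

Correlations between libraries are Pearson $R^2$ on $\log_2(x + 1)$ by
default. The original analysis never states its correlation scale, so the
raw scale is available but $R^2$ values are treated as qualitative
targets only, never asserted numerically against published ones.
Distribution summaries report a histogram (0.5 log2-unit bins), a normal
fitted by moments for overlay, and the sample skewness
$m_3 / m_2^{3/2}$ — positive when export dominates.

## qPCR quantification

Relative expression is $2^{-\Delta C_t}$ with
$\Delta C_t = \bar{C_t}(\text{miRNA}) - \bar{C_t}(\text{reference})$,
replicates averaged arithmetically on the $C_t$ scale first (the scale on
which the noise is approximately Gaussian). Amplification efficiency is
fixed at 2 — reactions in this design are optimized to double per cycle —
with an $E^{-\Delta C_t}$ variant available. The EV:cell ratio is then
$2^{\Delta C_t^{\text{cell}} - \Delta C_t^{\text{EV}}}$, an identity that
holds *exactly* on the log2 scale and is asserted as such. Undetermined
wells are missing data, never $C_t = 40$. Replicate spread is reported
both as the SD of $C_t$ and as the SD of per-replicate relative
expression, since conventions for error bars differ between labs.

## Cross-dataset rank concordance

Heterogeneous public datasets (sequencing, microarray, qPCR arrays) are
made comparable through ranks: each dataset is ranked by its own export
score — EV:cell ratio, or $\Delta C_t = C_t(\text{cells}) -
C_t(\text{EV})$ for qPCR arrays, defined in that direction so that larger
always means more exported — with average ranks at ties. The rank matrix
anchors rows on a reference dataset's ordering while every other dataset
keeps its **native** ranks, computed over its full detected set *before*
restriction; this is what makes "top-6 in its own dataset" meaningful and
it is tested directly by permuting the reference set. Blanks mark miRNAs
not detected or not assayed; a measured zero, by contrast, participates in
ranking. Concordance is summarized per pair by Spearman correlation over
co-detected miRNAs plus top-$k$ overlap (default $k = 6$).

## The synthetic-data generator

Since the original sequencing libraries are an external deposit, every
test runs on generated data with known ground truth. The generator
mirrors the study design: four libraries (cells/EVs ×
non-transfected/transfected) with

* cellular proportions from a log-normal with `sdlog = 2` — a heavy tail
  spanning the ~5 orders of magnitude of real miRNA expression;
* per-miRNA export propensities $e_i$ from a mixture: 10% exported
  (shift +4 log2 units), 10% retained (−2.5), the rest near zero with SD
  0.75 — export shifts more extreme than retention shifts, as observed;
* EV proportions $\propto$ cell proportions $\times 2^{e_i}$,
  renormalized. This compositional closure means realized log2 ratios
  equal $e_i$ minus a common constant, so recovery tests compare after
  median-centering;
* an optional spike seizing 32% of the cellular and 44% of the EV pool in
  the transfected condition (shares configurable independently, echoing
  the overexpression asymmetry);
* multinomial read counts at $10^6$ reads/library; isomiR end offsets
  with canonical mass 0.5 and the remainder mostly 3' variation;
  substitution errors at 0.002/base (typical Illumina-era rates); the
  full 3' adapter appended and reads truncated to 36 nt.

Ct tables derive from the same truth via
$C_t = \text{baseline} - \log_2(\text{abundance}) + \mathcal{N}(0,
\sigma)$ in triplicate. The dataset panel perturbs true log2 scores with
Gaussian noise and drops miRNAs with probability
$2 \cdot \text{dropout} \cdot (1 - \text{abundance percentile})$ —
detection tracks expression on every real platform, so highly expressed
species are essentially always observed while the mean dropout stays at
the nominal rate.

What the generator does *not* emulate: hairpin secondary structure,
ligation and PCR sequence biases (real isomiR spectra and counts are
biased in sequence-dependent ways), PCR duplicates, quality-score
structure, and cross-platform intensity distortions beyond monotone
noise. Passing tests therefore demonstrate correctness of the
computational pipeline under a faithful sampling model, not robustness to
every artifact of real library preparation.

## Numerical choices and degenerate inputs

* Alignment and trimming treat any symbol outside {A, C, G, T} (after
  U→T) as a mismatch, even against itself; degenerate bases can never
  create placements.
* Zero RPMM on either side makes the log2 ratio `NA` (an explicit
  undefined marker), never silently 0; a zero-depth library is an error
  naming the library.
* Renormalization refuses to exclude a library's entire expressed
  content; rank matrices require at least 2 detected miRNAs per dataset;
  pairs sharing fewer than 3 miRNAs are marked not computable rather than
  reported as a meaningless coefficient.
* Ties: average ranks in datasets (platform-agnostic), lexicographic ids
  in released/retained lists (deterministic output).
* Display rounding follows the published convention (1 decimal for the
  released list, 2 for the retained list) via `format_export_table()`;
  internal values are never rounded.

## Problem sizes

The analysis workflow (`analysis/01…06`) simulates 100 miRNAs at 20,000
reads/library for the read-level stages — a scale at which the exhaustive
aligner finishes in seconds — and count-level analyses (propensity
recovery, renormalization exactness) at the study-scale depth of $10^6$
reads/library over 200–300 miRNAs. The acceptance script uses the same
sizes.

## Known limitations

The mature-assignment windows are surrogates for an undocumented
commercial pipeline; different window choices move a small fraction of
loop-proximal reads. Multi-mapper splitting is exact but the real
read-to-family assignment of paralogous miRNA clusters is not
identifiable from hairpin alignment alone. Published $R^2$ values and the
published cross-dataset panel depend on external datasets and an
unstated correlation scale, so they are reproduced qualitatively
(property-based bounds on simulation), not numerically. The two
transfected-condition display values documented as inconsistent in
`?hek293t_export_values` are carried as printed and excluded from formula
checks.
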