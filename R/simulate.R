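#' Simulation configuration for the cells/EVs sequencing design
#'
#' Defines the generative model behind all synthetic inputs: a heavy-tailed
#' (log-normal) cellular abundance distribution over `n_mirnas` species;
#' per-miRNA export propensities `e` drawn from a three-component mixture
#' (most miRNAs near zero, a minority strongly exported, a minority
#' retained, with the exported shifts more extreme than the retained ones);
#' EV proportions proportional to cell proportions tilted by `2^e` and
#' renormalized; an optional overexpression spike that seizes a fixed
#' fraction of the cell and EV read pools (defaults echo an overexpressed
#' miRNA reaching 32% of cellular and 44% of EV reads); isomiR end-offset
#' structure with the canonical form holding about half the reads;
#' per-base substitution error; and a 3' adapter appended to every read.
#'
#' @param n_mirnas Number of miRNA species.
#' @param hairpin_length Hairpin length, nt.
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   (unnormalized) cellular abundances; `sdlog = 2` spans the several
#'   orders of magnitude typical of miRNA expression.
#' @param p_exported,p_retained Mixture weights of the strongly exported /
#'   retained components.
#' @param delta_exported,delta_retained Mean |log2| shift of those
#'   components.
#' @param sigma0 SD of the baseline (and component) log2 propensity noise.
#' @param spike `NULL`, or a list with `mature_id` (`NULL` = pick the
#'   first simulated miRNA), `cell_fraction`, `ev_fraction`.
#' @param reads_per_library Sequencing depth per library.
#' @param isomir_offsets Data frame `offset5`, `offset3`, `prob` giving
#'   the isomiR end-shift distribution; default puts mass 0.5 on the
#'   canonical form and the rest mostly on 3' variation.
#' @param error_rate Per-base substitution probability.
#' @param read_length Instrument read length, nt (insert plus adapter are
#'   truncated to this).
#' @param adapter 3' adapter sequence appended to simulated reads.
#' @param seed Integer seed making every generator deterministic.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_mirnas = 300L, hairpin_length = 80L,
                              abundance_meanlog = 0, abundance_sdlog = 2,
                              p_exported = 0.10, p_retained = 0.10,
                              delta_exported = 4, delta_retained = 2.5,
                              sigma0 = 0.75,
                              spike = NULL,
                              reads_per_library = 1e6,
                              isomir_offsets = NULL,
                              error_rate = 0.002,
                              read_length = 36L,
                              adapter = "ATCTCGTATGCCGTCTTCTGCTTG",
                              seed = 1L) {
  if (is.null(isomir_offsets))
    isomir_offsets <- data.frame(
      offset5 = c(0L, 0L, 0L, 0L, -1L, 1L, 0L),
      offset3 = c(0L, -1L, 1L, -2L, 0L, 0L, 2L),
      prob = c(0.50, 0.15, 0.10, 0.05, 0.08, 0.07, 0.05))
  if (abs(sum(isomir_offsets$prob) - 1) > 1e-8)
    stop_fmt("isomiR offset probabilities must sum to 1")
  if (p_exported + p_retained > 1)
    stop_fmt("mixture weights must sum to at most 1")
  if (!is.null(spike)) {
    if (spike$cell_fraction >= 1 || spike$ev_fraction >= 1)
      stop_fmt("spike pool fractions must be < 1")
    if (is.null(spike$mature_id)) spike$mature_id <- NA_character_
  }
  if (reads_per_library <= 0) stop_fmt("reads_per_library must be positive")
  structure(list(n_mirnas = as.integer(n_mirnas),
                 hairpin_length = as.integer(hairpin_length),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 p_exported = p_exported, p_retained = p_retained,
                 delta_exported = delta_exported,
                 delta_retained = delta_retained, sigma0 = sigma0,
                 spike = spike, reads_per_library = reads_per_library,
                 isomir_offsets = isomir_offsets, error_rate = error_rate,
                 read_length = as.integer(read_length),
                 adapter = norm_seq(adapter), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a hairpin reference with one mature arm per hairpin
#'
#' Mature arms of 20-23 nt are embedded in random hairpins; rejection
#' sampling enforces a pairwise Hamming distance of at least 5 between
#' mature sequences (over their common prefix) so reads map unambiguously.
#'
#' @param config A [simulation_config()].
#' @param seed Overrides `config$seed` when given.
#' @return A [hairpin_reference()] with matures `sim-mir-1` ...
#' @export
simulate_reference <- function(config, seed = config$seed) {
  set.seed(seed)
  n <- config$n_mirnas
  bases <- c("A", "C", "G", "T")
  matures <- character(0)
  max_attempts <- 200L * n + 200L
  attempts <- 0L
  while (length(matures) < n) {
    if ((attempts <- attempts + 1L) > max_attempts)
      stop_fmt(paste("could not place %d sufficiently distinct mature arms;",
                     "reduce n_mirnas or lengthen the arms"), n)
    len <- sample(20:23, 1L)
    cand <- paste(sample(bases, len, replace = TRUE), collapse = "")
    ok <- TRUE
    for (m in matures) {
      k <- min(nchar(m), len)
      d <- sum(strsplit(substr(cand, 1, k), "")[[1]] !=
                 strsplit(substr(m, 1, k), "")[[1]])
      if (d < 5L) { ok <- FALSE; break }
    }
    if (ok) matures <- c(matures, cand)
  }
  ids <- sprintf("sim-mir-%d", seq_len(n))
  hp <- character(n)
  starts <- integer(n)
  for (i in seq_len(n)) {
    len <- nchar(matures[i])
    start <- sample(5:(config$hairpin_length - len - 4L), 1L)
    flank5 <- paste(sample(bases, start - 1L, replace = TRUE), collapse = "")
    flank3 <- paste(sample(bases, config$hairpin_length - start - len + 1L,
                           replace = TRUE), collapse = "")
    hp[i] <- paste0(flank5, matures[i], flank3)
    starts[i] <- start
  }
  hairpin_reference(setNames(hp, paste0(ids, "-hp")),
                    data.frame(hairpin_id = paste0(ids, "-hp"),
                               mature_id = ids, start = starts,
                               end = starts + nchar(matures) - 1L))
}

# Draw cellular proportions, export propensities and the derived EV
# proportions; apply the overexpression spike to the transfected condition.
simulate_truth <- function(config, mature_ids, seed = config$seed) {
  set.seed(seed + 1L)
  n <- config$n_mirnas
  stopifnot(length(mature_ids) == n)
  ab <- stats::rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  cell <- ab / sum(ab)
  comp <- sample(c("exported", "retained", "baseline"), n, replace = TRUE,
                 prob = c(config$p_exported, config$p_retained,
                          1 - config$p_exported - config$p_retained))
  e <- rnorm(n, 0, config$sigma0)
  e[comp == "exported"] <- e[comp == "exported"] + config$delta_exported
  e[comp == "retained"] <- e[comp == "retained"] - config$delta_retained
  ev <- cell * 2^e
  ev <- ev / sum(ev)
  names(cell) <- names(ev) <- names(e) <- mature_ids

  apply_spike <- function(p, frac, id) {
    stopifnot(id %in% names(p))
    out <- p
    out[id] <- 0
    out <- out * (1 - frac) / sum(out)
    out[id] <- frac
    out
  }
  spike <- config$spike
  if (!is.null(spike) && is.na(spike$mature_id))
    spike$mature_id <- mature_ids[1]
  cell_tf <- cell
  ev_tf <- ev
  if (!is.null(spike)) {
    cell_tf <- apply_spike(cell, spike$cell_fraction, spike$mature_id)
    ev_tf <- apply_spike(ev, spike$ev_fraction, spike$mature_id)
  }
  structure(list(cell_proportions = cell, ev_proportions = ev,
                 cell_proportions_transfected = cell_tf,
                 ev_proportions_transfected = ev_tf,
                 e = e, component = setNames(comp, mature_ids),
                 spike = spike),
            class = "ground_truth")
}

#' Simulate per-library read counts from the generative model
#'
#' Draws one multinomial count vector per library (cells and EVs, for the
#' non-transfected and - when a spike is configured - transfected
#' conditions) at `reads_per_library` depth. This is the exact count-level
#' view of the read simulator: with error-free reads and canonical-only
#' isomiRs, [count_libraries()] on the simulated reads reproduces these
#' counts.
#'
#' @param config A [simulation_config()].
#' @param mature_ids miRNA ids (default from [simulate_reference()]
#'   naming).
#' @param seed Overrides `config$seed`.
#' @return List with `counts` (a [count_table()]), `truth` (the
#'   `ground_truth`), and `pairing` (a [library_pairing()]).
#' @export
simulate_counts <- function(config,
                            mature_ids = sprintf("sim-mir-%d",
                                                 seq_len(config$n_mirnas)),
                            seed = config$seed) {
  truth <- simulate_truth(config, mature_ids, seed)
  set.seed(seed + 2L)
  depth <- config$reads_per_library
  props <- list(cell_nt = truth$cell_proportions,
                ev_nt = truth$ev_proportions)
  if (!is.null(config$spike)) {
    props$cell_tf <- truth$cell_proportions_transfected
    props$ev_tf <- truth$ev_proportions_transfected
  }
  mat <- vapply(props, function(p) rmultinom(1L, depth, p)[, 1L],
                numeric(length(mature_ids)))
  rownames(mat) <- mature_ids
  pairing <- if (is.null(config$spike)) {
    library_pairing(nt = c(cell = "cell_nt", ev = "ev_nt"))
  } else {
    library_pairing(nt = c(cell = "cell_nt", ev = "ev_nt"),
                    tf = c(cell = "cell_tf", ev = "ev_tf"))
  }
  list(counts = count_table(mat), truth = truth, pairing = pairing)
}

# Build read sequences for one library from a per-miRNA count vector.
simulate_reads_one <- function(counts_vec, ref, config, lib, cond) {
  mat <- ref$matures
  total <- sum(counts_vec)
  if (total == 0L)
    return(list(reads = read_set(character(0), character(0), lib, cond),
                records = NULL))
  idx <- rep(seq_along(counts_vec), counts_vec)
  n <- length(idx)
  off_i <- sample(nrow(config$isomir_offsets), n, replace = TRUE,
                  prob = config$isomir_offsets$prob)
  o5 <- config$isomir_offsets$offset5[off_i]
  o3 <- config$isomir_offsets$offset3[off_i]
  m <- match(names(counts_vec)[idx], mat$mature_id)
  hp_id <- mat$hairpin_id[m]
  hp_len <- nchar(ref$sequences)[hp_id]
  from <- pmax(1L, mat$start[m] + o5)
  to <- pmin(hp_len, mat$end[m] + o3)
  o5 <- from - mat$start[m]  # realized offsets after clamping
  o3 <- to - mat$end[m]
  inserts <- unname(substr(ref$sequences[hp_id], from, to))
  n_err <- integer(n)
  if (config$error_rate > 0) {
    bases <- c("A", "C", "G", "T")
    split_ins <- strsplit(inserts, "")
    for (i in seq_len(n)) {
      hit <- which(runif(nchar(inserts[i])) < config$error_rate)
      if (length(hit)) {
        s <- split_ins[[i]]
        for (p in hit) s[p] <- sample(setdiff(bases, s[p]), 1L)
        inserts[i] <- paste(s, collapse = "")
        n_err[i] <- length(hit)
      }
    }
  }
  seqs <- substr(paste0(inserts, config$adapter), 1L, config$read_length)
  ids <- sprintf("%s_%s_r%06d", lib, cond, seq_len(n))
  list(reads = read_set(ids, seqs, lib, cond),
       records = tibble(read_id = ids, mature_id = names(counts_vec)[idx],
                        offset5 = o5, offset3 = o3, n_errors = n_err,
                        insert = substr(inserts, 1L, config$read_length)))
}

#' Simulate full sequencing libraries (reads with adapters)
#'
#' Per-miRNA counts are drawn as in [simulate_counts()]; each read is then
#' given isomiR end offsets, substitution errors, and the 3' adapter, and
#' truncated to the instrument read length. Ground truth records the
#' source miRNA, realized offsets and injected error count of every read.
#'
#' @param config A [simulation_config()].
#' @param ref A [hairpin_reference()] from [simulate_reference()].
#' @param seed Overrides `config$seed`.
#' @return List: `readsets` (named list of `read_set`), `counts`
#'   ([count_table()] of true source counts), `truth` (`ground_truth`
#'   with a `read_records` tibble), `pairing`.
#' @export
simulate_libraries <- function(config, ref, seed = config$seed) {
  sim <- simulate_counts(config, ref$matures$mature_id, seed)
  set.seed(seed + 3L)
  libs <- colnames(sim$counts$counts)
  readsets <- list()
  records <- list()
  for (lib in libs) {
    compartment <- if (startsWith(lib, "cell")) "cell" else "EV"
    cond <- sub("^[^_]*_", "", lib)
    one <- simulate_reads_one(sim$counts$counts[, lib], ref, config,
                              compartment, cond)
    readsets[[lib]] <- one$reads
    if (!is.null(one$records)) {
      one$records$library <- lib
      records[[lib]] <- one$records
    }
  }
  sim$truth$read_records <- dplyr::bind_rows(records)
  list(readsets = readsets, counts = sim$counts, truth = sim$truth,
       pairing = sim$pairing)
}

#' Simulate an RT-qPCR Ct table from ground-truth abundances
#'
#' Ct values follow `baseline - log2(abundance)` plus Gaussian replicate
#' noise, i.e. a doubling per cycle; triplicates by default.
#' Zero-abundance miRNAs yield missing wells (no rows).
#'
#' @param truth A `ground_truth` (from [simulate_counts()] /
#'   [simulate_libraries()]).
#' @param reference_mirna Normalizer miRNA id (must have nonzero
#'   abundance).
#' @param noise_sd Replicate noise SD, cycles.
#' @param n_replicates Technical replicates per well.
#' @param baseline Ct of a (hypothetical) abundance-1 species; with
#'   proportions as abundances the default 10 puts typical wells in the
#'   usual 10-40 cycle range.
#' @param condition `"nt"` or `"tf"` proportions.
#' @param seed Integer seed.
#' @return A [ct_table()] with samples `cell` and `EV`.
#' @export
simulate_ct_table <- function(truth, reference_mirna, noise_sd = 0.2,
                              n_replicates = 3L, baseline = 10,
                              condition = c("nt", "tf"), seed = 1L) {
  condition <- match.arg(condition)
  set.seed(seed)
  ab <- if (condition == "nt")
    list(cell = truth$cell_proportions, EV = truth$ev_proportions)
  else
    list(cell = truth$cell_proportions_transfected,
         EV = truth$ev_proportions_transfected)
  if (!reference_mirna %in% names(ab$cell) || ab$cell[reference_mirna] <= 0)
    stop_fmt("reference miRNA '%s' absent from ground truth", reference_mirna)
  rows <- list()
  for (s in names(ab)) {
    p <- ab[[s]]
    p <- p[p > 0]  # zero abundance -> missing wells
    n <- length(p)
    rows[[s]] <- tibble(
      sample = s,
      mirna = rep(names(p), each = n_replicates),
      replicate = rep(seq_len(n_replicates), n),
      ct = rep(baseline - log2(p), each = n_replicates) +
        rnorm(n * n_replicates, 0, noise_sd))
  }
  df <- dplyr::bind_rows(rows)
  ct_table(df$sample, df$mirna, df$replicate, df$ct, reference_mirna)
}

#' Simulate a panel of heterogeneous export datasets
#'
#' Emulates a collection of public cells-vs-EVs expression datasets from
#' different platforms. Each dataset perturbs the true log2 export ratios
#' with Gaussian noise (`rank_noise`, log2 units) and drops miRNAs at
#' random. Detection tracks abundance: the per-miRNA dropout probability
#' scales with `2 * dropout * (1 - abundance percentile)`, so
#' highly-expressed species are essentially always detected, as on real
#' platforms, while the mean dropout stays near `dropout`. Sequencing and
#' microarray datasets report EV:cell ratios; qPCR-array datasets report
#' the equivalent delta-Ct (cells - EV).
#'
#' @param truth A `ground_truth`.
#' @param n_datasets Number of datasets.
#' @param platforms Character vector recycled over datasets.
#' @param rank_noise SD of the log2-scale score perturbation.
#' @param dropout Mean random-detection dropout probability.
#' @param seed Integer seed.
#' @return List of [dataset_measure()] objects named `dataset_1` ...
#' @export
simulate_dataset_panel <- function(truth, n_datasets = 8L,
                                   platforms = c("microarray", "qpcr_array"),
                                   rank_noise = 1.0, dropout = 0.2,
                                   seed = 1L) {
  if (n_datasets < 2L) stop_fmt("need at least 2 datasets")
  set.seed(seed)
  true_log2 <- log2(truth$ev_proportions) - log2(truth$cell_proportions)
  ids <- names(true_log2)
  abundance <- pmax(truth$cell_proportions, truth$ev_proportions)
  pct <- rank(abundance) / length(abundance)
  p_miss <- pmin(1, pmax(0, 2 * dropout * (1 - pct)))
  platforms <- rep_len(platforms, n_datasets)
  out <- list()
  for (d in seq_len(n_datasets)) {
    noisy <- true_log2 + rnorm(length(ids), 0, rank_noise)
    keep <- runif(length(ids)) >= p_miss & is.finite(noisy)
    scores <- if (platforms[d] == "qpcr_array") noisy[keep]
    else 2^noisy[keep]
    out[[sprintf("dataset_%d", d)]] <-
      dataset_measure(sprintf("dataset_%d", d), platforms[d],
                      scores = scores)
  }
  out
}
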