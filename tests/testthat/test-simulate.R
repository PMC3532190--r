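test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- simulation_config(n_mirnas = 10, reads_per_library = 300, seed = 5)
  ref1 <- simulate_reference(cfg)
  ref2 <- simulate_reference(cfg)
  expect_identical(ref1$sequences, ref2$sequences)
  fa1 <- tempfile(); fa2 <- tempfile(); tsv <- tempfile()
  write_hairpin_reference(ref1, fa1, tsv)
  write_hairpin_reference(ref2, fa2, tsv)
  expect_identical(readLines(fa1), readLines(fa2))

  s1 <- simulate_libraries(cfg, ref1)
  s2 <- simulate_libraries(cfg, ref1)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$readsets$cell_nt$sequence, s2$readsets$cell_nt$sequence)
})

test_that("simulated references satisfy the reference invariants", {
  cfg <- simulation_config(n_mirnas = 50, seed = 31)
  ref <- simulate_reference(cfg)
  expect_equal(length(ref$sequences), 50L)
  expect_equal(nrow(ref$matures), 50L)
  lens <- nchar(mature_sequences(ref))
  expect_true(all(lens >= 20 & lens <= 23))
  # pairwise distinctness: aligning matures against the reference places
  # each uniquely at 0 mismatches
  hits <- align_reads(mature_sequences(ref), ref, max_mismatches = 2)
  zero <- hits[hits$mismatches == 0, ]
  expect_equal(nrow(zero), 50L)
  expect_equal(zero$hairpin_id,
               ref$matures$hairpin_id[match(zero$read_id,
                                            ref$matures$mature_id)])
  cfg1 <- simulation_config(n_mirnas = 1, seed = 2)
  ref1 <- simulate_reference(cfg1)
  expect_equal(length(ref1$sequences), 1L)
})

test_that("simulated FASTQ round-trips through files at the declared count", {
  cfg <- simulation_config(n_mirnas = 8, reads_per_library = 1000, seed = 77)
  ref <- simulate_reference(cfg)
  sim <- simulate_libraries(cfg, ref)
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$readsets$cell_nt, fq)
  back <- read_fastq(fq, "cell", "nt")
  expect_equal(nrow(back), 1000L)
  expect_equal(back$sequence, sim$readsets$cell_nt$sequence)
})

test_that("a 32% cell-pool spike lands near 320,000 RPMM at 1e6 reads", {
  cfg <- simulation_config(n_mirnas = 150, reads_per_library = 1e6,
                           spike = list(mature_id = NULL,
                                        cell_fraction = 0.32,
                                        ev_fraction = 0.44),
                           seed = 29)
  sim <- simulate_counts(cfg)
  spike_id <- sim$truth$spike$mature_id
  expr <- rpmm(sim$counts)
  expect_lt(abs(expr$values[spike_id, "cell_tf"] - 320000), 2000)
  expect_lt(abs(expr$values[spike_id, "ev_tf"] - 440000), 2100)
  # non-transfected pools are spike-free by construction
  expect_equal(unname(sim$truth$cell_proportions_transfected[spike_id]), 0.32)
  expect_equal(unname(sim$truth$ev_proportions_transfected[spike_id]), 0.44)
})

test_that("null export propensities give ratios centered at zero with no skew", {
  cfg <- simulation_config(n_mirnas = 300, reads_per_library = 1e6,
                           p_exported = 0, p_retained = 0, sigma0 = 0,
                           seed = 71)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$e == 0))
  expr <- rpmm(sim$counts)
  tab <- build_export_table(expr, sim$counts, sim$pairing,
                            read_threshold = 100)
  # sampling noise at low counts is heavy-tailed, so summarize the
  # well-measured species; their ratios are tight and symmetric
  d <- distribution_summary(tab[tab$expressed, ])
  expect_gt(d$n, 50)
  expect_lt(abs(d$fitted_normal[["mean"]]), 0.1)
  expect_lt(abs(d$skewness), 0.75)
})

test_that("ground-truth proportion vectors are simplex-valued and consistent", {
  cfg <- simulation_config(n_mirnas = 40, seed = 3,
                           spike = list(mature_id = NULL,
                                        cell_fraction = 0.32,
                                        ev_fraction = 0.44))
  sim <- simulate_counts(cfg)
  t <- sim$truth
  for (p in list(t$cell_proportions, t$ev_proportions,
                 t$cell_proportions_transfected,
                 t$ev_proportions_transfected))
    expect_equal(sum(p), 1)
  # EV proportions are the cell proportions tilted by 2^e, renormalized
  tilt <- t$cell_proportions * 2^t$e
  expect_equal(unname(t$ev_proportions), unname(tilt / sum(tilt)))
})

test_that("a strongly exported species tops most panel datasets", {
  cfg <- simulation_config(n_mirnas = 150, seed = 17)
  sim <- simulate_counts(cfg)
  truth <- sim$truth
  # plant one extreme exporter with solid expression, echoing the design
  star <- names(sort(truth$cell_proportions, decreasing = TRUE))[10]
  truth$e[star] <- 13
  ev <- truth$cell_proportions * 2^truth$e
  truth$ev_proportions <- ev / sum(ev)
  panel <- simulate_dataset_panel(truth, n_datasets = 8, rank_noise = 1.0,
                                  dropout = 0.2, seed = 18)
  native_rank <- vapply(panel, function(d) {
    r <- rank_dataset(d)
    r$rank[match(star, r$mature_id)]
  }, numeric(1))
  expect_gte(sum(native_rank <= 6, na.rm = TRUE), 6)
})

test_that("panel dropout produces the expected blank fraction uniformly at dropout=0.5", {
  cfg <- simulation_config(n_mirnas = 200, seed = 23)
  sim <- simulate_counts(cfg)
  # uniform dropout: flatten the abundance-detection link by equal props
  truth <- sim$truth
  panel <- simulate_dataset_panel(truth, n_datasets = 10, rank_noise = 0.5,
                                  dropout = 0.5, seed = 24)
  detected <- vapply(panel, nrow, numeric(1))
  blank_frac <- 1 - mean(detected) / cfg$n_mirnas
  expect_lt(abs(blank_frac - 0.5), 0.05)
  # zero noise, zero dropout: all pairwise Spearman = 1
  panel0 <- simulate_dataset_panel(truth, n_datasets = 4, rank_noise = 0,
                                   dropout = 0, seed = 25)
  rm0 <- build_rank_matrix(rank_dataset(panel0[[1]]), panel0[-1])
  cc <- concordance(rm0)
  expect_true(all(cc$spearman == 1))
})

test_that("noiseless Ct tables reproduce realized abundance ratios exactly", {
  cfg <- simulation_config(n_mirnas = 30, seed = 9)
  sim <- simulate_counts(cfg)
  truth <- sim$truth
  ref_id <- names(truth$e)[1]
  ct <- simulate_ct_table(truth, reference_mirna = ref_id, noise_sd = 0,
                          seed = 10)
  true_log2 <- log2(truth$ev_proportions) - log2(truth$cell_proportions)
  for (m in names(truth$e)[2:6]) {
    got <- log2(qpcr_ev_cell_ratio(ct, m, "cell", "EV"))
    expect_equal(got, unname(true_log2[m] - true_log2[ref_id]),
                 tolerance = 1e-9)
  }
})
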