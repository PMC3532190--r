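test_that("log2(EV/cell) reproduces published worked examples at printed rounding", {
  # released list prints 1 decimal, retained list 2 decimals
  expect_equal(round(log2_ev_cell(0.4, 3945.0), 1), 13.3)
  expect_equal(round(log2_ev_cell(0.4, 2475.0), 1), 12.6)
  expect_equal(round(log2_ev_cell(10.4, 1321.2), 1), 7.0)
  expect_equal(round(log2_ev_cell(317863.3, 440496.3), 1), 0.5)
  expect_equal(round(log2_ev_cell(24.3, 2347.5), 1), 6.6)
  expect_equal(round(log2_ev_cell(105.7, 3900.0), 1), 5.2)
  expect_equal(round(log2_ev_cell(1.7, 7982.5), 1), 12.2)
  expect_equal(round(log2_ev_cell(1342.24, 135.00), 2), -3.31)
  expect_equal(round(log2_ev_cell(2411.56, 435.00), 2), -2.47)
  expect_equal(round(log2_ev_cell(7225.49, 2100.00), 2), -1.78)
})

test_that("log2 ratio identities and undefined-value handling", {
  x <- c(0.01, 1, 42, 1e6)
  expect_equal(log2_ev_cell(x, x), rep(0, 4))
  expect_true(is.na(log2_ev_cell(0, 100)))
  expect_true(is.na(log2_ev_cell(100, 0)))
  expect_equal(log2_ev_cell(c(2, 0), c(8, 5)), c(2, NA))
})

test_that("the bundled HEK293T values rank mir-451 most released, mir-218 most retained", {
  vals <- hek293t_export_values()
  nt <- vals[vals$condition == "non_transfected", ]
  ratio <- log2_ev_cell(nt$cell_rpmm, nt$ev_rpmm)
  expect_equal(nt$mature_id[which.max(ratio)], "mir-451")
  expect_equal(nt$mature_id[which.min(ratio)], "mir-218")
  # recomputed ratios match the printed display at its rounding
  rel <- nt$list == "released"
  expect_equal(round(ratio[rel], 1), nt$log2_printed[rel])
  expect_equal(round(ratio[!rel], 2), nt$log2_printed[!rel])
})

make_export_fixture <- function(cell, ev, reads_cell = NULL, reads_ev = NULL,
                                threshold = 0) {
  ids <- names(cell)
  vals <- cbind(cell = cell, ev = ev)
  expr <- expression_matrix(vals, c(cell = 1e6, ev = 1e6))
  if (is.null(reads_cell)) reads_cell <- cell
  if (is.null(reads_ev)) reads_ev <- ev
  ct <- count_table(cbind(cell = reads_cell, ev = reads_ev))
  build_export_table(expr, ct, library_pairing(x = c(cell = "cell", ev = "ev")),
                     read_threshold = threshold)
}

test_that("equal cell/EV profiles classify everything as similar", {
  v <- setNames(c(100, 2000, 5, 40), sprintf("m%d", 1:4))
  tab <- make_export_fixture(v, v)
  expect_true(all(tab$class == "similar"))
  rr <- released_retained(tab)
  expect_equal(nrow(rr$released), 0L)
  expect_equal(nrow(rr$retained), 0L)
})

test_that("expression flag uses raw reads with strict > threshold", {
  v <- setNames(c(10, 10, 10), c("a", "b", "c"))
  tab <- make_export_fixture(v, v * 8,
                             reads_cell = c(a = 1000, b = 1001, c = 0),
                             reads_ev = c(a = 0, b = 0, c = 1200),
                             threshold = 1000)
  expect_equal(setNames(tab$expressed, tab$mature_id),
               c(a = FALSE, b = TRUE, c = TRUE))
  expect_equal(tab$class[tab$mature_id == "a"], "undetected")
  expect_equal(tab$class[tab$mature_id == "b"], "released")
})

test_that("released/retained lists are disjoint, exhaustive and deterministically tied", {
  v <- setNames(c(10, 20, 30, 40, 50, 60), sprintf("m%d", 1:6))
  ev <- v * c(8, 8, 1, 1, 1 / 8, 1 / 8)
  tab <- make_export_fixture(v, ev)
  rr <- released_retained(tab)
  expect_equal(rr$released$mature_id, c("m1", "m2"))  # equal ratios: id order
  expect_equal(rr$retained$mature_id, c("m5", "m6"))
  expect_length(intersect(rr$released$mature_id, rr$retained$mature_id), 0)
  expect_setequal(tab$mature_id[tab$class == "similar"], c("m3", "m4"))
})

test_that("swapping compartments negates every ratio (antisymmetry)", {
  set.seed(123)
  cell <- setNames(rlnorm(50, 5, 2), sprintf("m%d", 1:50))
  ev <- setNames(rlnorm(50, 5, 2), sprintf("m%d", 1:50))
  fwd <- make_export_fixture(cell, ev)
  rev <- make_export_fixture(ev, cell)
  expect_equal(fwd$log2_ratio, -rev$log2_ratio)
  d_f <- distribution_summary(fwd)
  d_r <- distribution_summary(rev)
  expect_equal(d_f$skewness, -d_r$skewness, tolerance = 1e-12)
  expect_equal(d_f$fraction_similar, d_r$fraction_similar)
})

test_that("distribution summary: symmetry, construction skew, similar fraction", {
  set.seed(31)
  n <- 5000  # |skewness| of a symmetric sample concentrates as sqrt(6/n)
  sym <- setNames(2^rnorm(n, 0, 2), sprintf("m%d", 1:n))
  base <- setNames(rep(1000, n), sprintf("m%d", 1:n))
  d <- distribution_summary(make_export_fixture(base, base * sym))
  expect_lt(abs(d$skewness), 0.1)
  expect_equal(sum(d$counts), n)
  expect_equal(d$n, n)

  # 10% strongly exported species skew the distribution right
  shifted <- sym
  shifted[seq_len(n / 10)] <- shifted[seq_len(n / 10)] * 2^6
  d2 <- distribution_summary(make_export_fixture(base, base * shifted))
  expect_gt(d2$skewness, 0.5)

  # ratios drawn strictly inside (-1, 1) are all "similar"
  inside <- setNames(2^runif(100, -0.99, 0.99), sprintf("m%d", 1:100))
  d3 <- distribution_summary(make_export_fixture(base[1:100], base[1:100] * inside))
  expect_equal(d3$fraction_similar, 1.0)

  expect_error(distribution_summary(make_export_fixture(
    setNames(c(1, 2), c("a", "b")), setNames(c(1, 2), c("a", "b")))),
    "at least 3")
})

test_that("open and closed similar bands differ exactly at the endpoints", {
  base <- setNames(rep(100, 4), c("a", "b", "c", "d"))
  ev <- base * 2^c(-1, 0, 1, 3)
  tab <- make_export_fixture(base, ev)
  open <- distribution_summary(tab, similar_band = "open")
  closed <- distribution_summary(tab, similar_band = "closed")
  expect_equal(open$fraction_similar, 1 / 4)
  expect_equal(closed$fraction_similar, 3 / 4)
})

test_that("correlation report: identity, independence, and resampling bounds", {
  set.seed(55)
  ids <- sprintf("m%d", 1:200)
  a <- setNames(rlnorm(200, 6, 2), ids)
  expect_equal(correlation_report(a, a)$r_squared, 1.0)

  b <- setNames(rlnorm(200, 6, 2), ids)
  expect_lt(correlation_report(a, b)$r_squared, 0.1)

  # two multinomial resamples of one abundance vector at 1e6 reads
  p <- a / sum(a)
  r1 <- setNames(rmultinom(1, 1e6, p)[, 1], ids)
  r2 <- setNames(rmultinom(1, 1e6, p)[, 1], ids)
  expect_gt(correlation_report(r1, r2, scale = "log")$r_squared, 0.95)

  expect_error(correlation_report(a[1:2], b[1:2]), "at least 3")
})

test_that("a balanced spike leaves log2 ratios of other miRNAs unchanged", {
  # excluding a miRNA holding the same pool share s in cells and EVs
  # rescales both compartments by 1/(1-s): ratios cancel exactly
  set.seed(9)
  ids <- sprintf("m%d", 1:30)
  cell <- setNames(c(300, rpois(29, 50) + 1), ids)
  ev <- setNames(c(300, rpois(29, 80) + 1), ids)
  cell[1] <- sum(cell[-1])  # spike holds 50% of both pools
  ev[1] <- sum(ev[-1])
  expr <- expression_matrix(cbind(cell = cell / sum(cell) * 1e6,
                                  ev = ev / sum(ev) * 1e6),
                            c(cell = sum(cell), ev = sum(ev)))
  before <- log2_ev_cell(expr$values[-1, "cell"], expr$values[-1, "ev"])
  ren <- exclude_and_renormalize(expr, ids[1])
  after <- log2_ev_cell(ren$values[, "cell"], ren$values[, "ev"])
  expect_equal(after, before, tolerance = 1e-12)
})

test_that("export ratios recover simulated propensities after median-centering", {
  cfg <- simulation_config(n_mirnas = 200, reads_per_library = 1e6, seed = 41)
  sim <- simulate_counts(cfg)
  expr <- rpmm(sim$counts)
  tab <- build_export_table(expr, sim$counts, sim$pairing,
                            read_threshold = 1000)
  est <- setNames(tab$log2_ratio, tab$mature_id)
  truth <- sim$truth
  expected_cell <- truth$cell_proportions * cfg$reads_per_library
  expected_ev <- truth$ev_proportions * cfg$reads_per_library
  eligible <- names(which(expected_cell >= 1000 & expected_ev >= 1000))
  expect_gt(length(eligible), 20)
  err <- (est[eligible] - median(est[eligible])) -
    (truth$e[eligible] - median(truth$e[eligible]))
  expect_gte(mean(abs(err) <= 0.2), 0.95)
  # rank agreement with the true propensities
  expect_gt(cor(est[eligible], truth$e[eligible], method = "spearman"), 0.95)
})
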