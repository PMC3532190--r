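test_that("ranking: rank 1 is most exported, ties averaged", {
  m <- dataset_measure("d1", "microarray",
                       scores = c(a = 8, b = 2, c = 0.5))
  r <- rank_dataset(m)
  expect_equal(setNames(r$rank, r$mature_id), c(a = 1, b = 2, c = 3))

  tied <- rank_dataset(dataset_measure("d2", "microarray",
                                       scores = c(a = 5, b = 5, c = 1)))
  expect_equal(tied$rank[tied$mature_id %in% c("a", "b")], c(1.5, 1.5))
})

test_that("qPCR delta-Ct ranking equals ratio ranking (monotone equivalence)", {
  set.seed(4)
  ratios <- setNames(2^rnorm(40, 0, 3), sprintf("m%d", 1:40))
  by_ratio <- rank_dataset(dataset_measure("seq", "sequencing",
                                           scores = ratios))
  # delta Ct (cells - EV) = log2 ratio when amplification doubles per cycle
  by_dct <- rank_dataset(dataset_measure("qp", "qpcr_array",
                                         scores = log2(ratios)))
  expect_equal(by_dct$rank, by_ratio$rank)
  # any strictly monotone transform leaves ranks unchanged
  by_mono <- rank_dataset(dataset_measure("mono", "microarray",
                                          scores = ratios^3 + 1))
  expect_equal(by_mono$rank, by_ratio$rank)
})

test_that("dataset_measure derives platform-appropriate scores from cell/EV values", {
  arr <- dataset_measure("a", "microarray", mature_id = c("x", "y"),
                         cell_value = c(10, 100), ev_value = c(40, 50))
  expect_equal(arr$score, c(4, 0.5))
  qp <- dataset_measure("q", "qpcr_array", mature_id = c("x", "y"),
                        cell_value = c(30, 25), ev_value = c(28, 27))
  expect_equal(qp$score, c(2, -2))  # Ct(cells) - Ct(EV)
})

test_that("rank matrix: reference ordering, native ranks, blanks", {
  ref <- rank_dataset(dataset_measure("ref", "sequencing",
                                      scores = c(a = 16, b = 4, c = 1, d = 0.25)))
  # identical dataset: two identical columns
  rm1 <- build_rank_matrix(ref, list(dataset_measure("copy", "sequencing",
                                                     scores = c(a = 16, b = 4, c = 1, d = 0.25))))
  expect_equal(rownames(rm1$ranks), c("a", "b", "c", "d"))
  expect_equal(unname(rm1$ranks[, "ref"]), unname(rm1$ranks[, "copy"]))
  expect_false(is.unsorted(rm1$ranks[, "ref"]))

  # a dataset missing half the reference miRNAs leaves exactly those blank
  half <- dataset_measure("half", "microarray", scores = c(b = 9, d = 3))
  rm2 <- build_rank_matrix(ref, list(half))
  expect_equal(which(is.na(rm2$ranks[, "half"])),
               c(a = 1L, c = 3L))
  expect_equal(unname(rm2$ranks[c("b", "d"), "half"]), c(1, 2))
})

test_that("native ranks are computed before restriction to the reference set", {
  ref <- rank_dataset(dataset_measure("ref", "sequencing",
                                      scores = c(a = 8, b = 2)))
  other <- dataset_measure("o", "microarray",
                           scores = c(z = 100, a = 8, y = 5, b = 2))
  rm <- build_rank_matrix(ref, list(other))
  # a is the other dataset's 2nd most exported of its own 4, not 1st of 2
  expect_equal(unname(rm$ranks["a", "o"]), 2)
  expect_equal(unname(rm$ranks["b", "o"]), 4)
  expect_lte(max(rm$ranks[!is.na(rm$ranks[, "o"]), "o"]),
             rm$n_detected[["o"]])
  # decile bands come from the native detected count
  expect_equal(unname(rm$bands["a", "o"]), ceiling(2 / 4 * 10))
})

test_that("concordance: identical datasets, shuffled null, resampled profiles", {
  set.seed(71)
  ids <- sprintf("m%d", 1:100)
  scores <- setNames(2^rnorm(100, 0, 2), ids)
  ref <- rank_dataset(dataset_measure("ref", "sequencing", scores = scores))
  copy <- dataset_measure("copy", "sequencing", scores = scores)
  rm <- build_rank_matrix(ref, list(copy))
  cc <- concordance(rm, k = 6)
  expect_equal(cc$spearman, 1.0)
  expect_equal(cc$top_k_overlap, 6L)

  # independently shuffled scores: |rho| < 0.25 in at least 95% of replicates
  hits <- 0L
  for (i in 1:100) {
    shuf <- dataset_measure("shuf", "microarray",
                            scores = setNames(sample(scores), ids))
    rho <- concordance(build_rank_matrix(ref, list(shuf)))$spearman
    if (abs(rho) < 0.25) hits <- hits + 1L
  }
  expect_gte(hits, 95L)

  # two multinomial resamples of one export profile stay concordant
  p_cell <- setNames(rep(1 / 100, 100), ids)
  p_ev <- p_cell * scores / sum(p_cell * scores)
  r_cell1 <- rmultinom(1, 1e6, p_cell)[, 1]
  r_ev1 <- rmultinom(1, 1e6, p_ev)[, 1]
  r_cell2 <- rmultinom(1, 1e6, p_cell)[, 1]
  r_ev2 <- rmultinom(1, 1e6, p_ev)[, 1]
  d1 <- rank_dataset(dataset_measure("s1", "sequencing",
                                     scores = setNames(r_ev1 / r_cell1, ids)))
  d2 <- dataset_measure("s2", "sequencing",
                        scores = setNames(r_ev2 / r_cell2, ids))
  expect_gt(concordance(build_rank_matrix(d1, list(d2)))$spearman, 0.8)
})

test_that("pairs sharing fewer than 3 miRNAs are marked not computable", {
  ref <- rank_dataset(dataset_measure("ref", "sequencing",
                                      scores = c(a = 4, b = 2, c = 1)))
  sparse <- dataset_measure("sp", "microarray", scores = c(a = 1, z = 2))
  cc <- concordance(build_rank_matrix(ref, list(sparse)))
  expect_false(cc$computable)
  expect_true(is.na(cc$spearman))
})

test_that("dataset measures and rank matrices round-trip through TSV", {
  m <- dataset_measure("ds1", "microarray", mature_id = c("a", "b", "c"),
                       cell_value = c(10, 20, 5), ev_value = c(40, 10, 5))
  path <- tempfile(fileext = ".tsv")
  write_dataset_measure(m, path, cell_value = c(10, 20, 5),
                        ev_value = c(40, 10, 5))
  back <- read_dataset_measure(path)
  expect_equal(attr(back, "dataset_id"), "ds1")
  expect_equal(attr(back, "platform"), "microarray")
  expect_equal(back$score, m$score)

  rm <- build_rank_matrix(rank_dataset(m),
                          list(dataset_measure("ds2", "microarray",
                                               scores = c(a = 2, b = 1))))
  out <- tempfile(fileext = ".tsv")
  write_rank_matrix(rm, out)
  df <- read.delim(out)
  expect_equal(df$mature_id, rownames(rm$ranks))
})
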