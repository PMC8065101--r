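test_that("Mann-Whitney U and exact p match enumeration on small samples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)                       # 2 / C(6,3) labelings
  expect_equal(r$p, mw_enum_p(c(1, 2, 3), c(4, 5, 6)))

  # identical multisets: p = 1 within tolerance
  r <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p, 1, tolerance = 1e-6)

  # complete separation of two large groups
  r <- mann_whitney_u(1:30, 31:60)
  expect_lt(r$p, 1e-9)

  expect_error(mann_whitney_u(numeric(0), 1:3), "empty input")
})

test_that("exact p equals full enumeration for all partitions up to n = 10", {
  set.seed(77)
  for (n_tot in c(4, 6, 8, 10)) {
    for (nx in 1:(n_tot - 1)) {
      vals <- sample(seq_len(50), n_tot)   # distinct: the exact null applies
      x <- vals[seq_len(nx)]
      y <- vals[-seq_len(nx)]
      r <- mann_whitney_u(x, y)
      expect_equal(r$p, mw_enum_p(x, y), tolerance = 1e-12,
                   info = paste(n_tot, nx))
    }
  }
})

test_that("Mann-Whitney agrees with wilcox.test in both regimes", {
  set.seed(88)
  # exact regime
  x <- rnorm(8); y <- rnorm(12)
  r <- mann_whitney_u(x, y)
  w <- wilcox.test(x, y)
  expect_true(r$exact)
  expect_equal(r$U, unname(w$statistic))
  expect_equal(r$p, w$p.value)
  # approximate regime (ties force the corrected normal approximation)
  x <- sample(1:8, 30, TRUE); y <- sample(3:10, 40, TRUE)
  r <- mann_whitney_u(x, y)
  w <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_false(r$exact)
  expect_equal(r$p, w$p.value)
})

test_that("chi-square test matches hand computation", {
  r <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  r <- chi_square_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r$statistic, 40)   # Pearson, no continuity correction
  expect_equal(r$df, 1)

  r <- chi_square_test(matrix(c(5, 10, 15, 10, 10, 5), 2))
  expect_equal(r$df, 2)

  expect_error(chi_square_test(matrix(c(0, 0, 5, 5), 2)), "zero marginal")
})

test_that("bootstrap comparison is seeded, reproducible and degenerates correctly", {
  set.seed(1)
  pool <- rnorm(100)
  carriers <- rnorm(9)
  b1 <- bootstrap_compare(carriers, pool, n_controls = 30, iters = 50, seed = 7)
  b2 <- bootstrap_compare(carriers, pool, n_controls = 30, iters = 50, seed = 7)
  expect_identical(b1$p_iter, b2$p_iter)
  expect_equal(b1$p_corrected, median(b1$p_iter))

  # iters = 1 equals a single subsampled test
  b <- bootstrap_compare(carriers, pool, n_controls = 30, iters = 1, seed = 3)
  set.seed(3)
  ctrl <- sample(pool, 30)
  expect_equal(b$p_corrected, mann_whitney_u(carriers, ctrl)$p)

  expect_error(bootstrap_compare(carriers, rnorm(10), n_controls = 30,
                                 iters = 5, seed = 1),
               "pool smaller")
})

test_that("complete separation gives the minimal exact two-sided p", {
  pool <- seq_len(500)
  carriers <- 1000 + seq_len(9)   # every carrier exceeds every control
  b <- bootstrap_compare(carriers, pool, n_controls = 30, iters = 25, seed = 5)
  p_min <- 2 * pwilcox(9 * 30 - 1, 9, 30, lower.tail = FALSE)
  expect_equal(b$p_corrected, p_min)
  expect_true(all(b$p_iter == p_min))
})

test_that("stratified group summaries report medians, sizes and both p values", {
  cls <- data.frame(
    sample_id = c(paste0("P", 1:3), paste0("N", 1:40)),
    carrier_group = c(rep("PALB2", 3), rep("non_carrier", 40)),
    allelic_status = c(rep("biallelic", 3), rep(NA, 40)),
    stringsAsFactors = FALSE)
  vals <- setNames(c(2, 4, 6, rep(1:5, 8)), cls$sample_id)
  out <- suppressMessages(
    summarize_groups(vals, cls, metric = "toy", seed = 2, iters = 20))
  expect_equal(nrow(out), 1L)   # only the populated stratum is reported
  expect_equal(out$stratum, "PALB2_biallelic")
  expect_equal(out$n, 3L)
  expect_equal(out$group_summary, 4)
  expect_equal(out$reference_summary, 3)
  expect_true(out$p_raw >= 0 && out$p_raw <= 1)
  expect_true(out$p_bootstrap >= 0 && out$p_bootstrap <= 1)
})
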