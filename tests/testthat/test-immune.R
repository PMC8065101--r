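log2p1 <- function(x) log2(x + 1)

test_that("cytolytic index is the offset geometric mean on the linear scale", {
  expr <- matrix(log2p1(c(4, 4, 0, 0, 1, 100)), nrow = 2,
                 dimnames = list(c("GZMA", "PRF1"), c("A", "B", "C")))
  cyt <- cyt_index(expr)
  expect_equal(unname(cyt["A"]), 4.01)                       # equal expression
  expect_equal(unname(cyt["B"]), 0.01)                       # offset floor
  expect_equal(unname(cyt["C"]), sqrt(1.01 * 100.01))        # ~10.05
  expect_error(cyt_index(expr[1, , drop = FALSE]), "PRF1")
})

test_that("cytolytic index is monotone in each gene and sample-permutation invariant", {
  expr <- matrix(log2p1(c(2, 3, 5, 7)), nrow = 2,
                 dimnames = list(c("GZMA", "PRF1"), c("A", "B")))
  cyt <- cyt_index(expr)
  up <- expr
  up["GZMA", "A"] <- up["GZMA", "A"] + 1
  expect_gt(cyt_index(up)["A"], cyt["A"])
  perm <- expr[, c("B", "A")]
  expect_equal(unname(cyt_index(perm)[c("A", "B")]), unname(cyt[c("A", "B")]))
})

test_that("ssGSEA score is maximal when the set occupies the top ranks", {
  genes <- paste0("g", 1:10)
  expr <- matrix(10:1, ncol = 1, dimnames = list(genes, "S"))
  top <- ssgsea_score(expr, genes[1:3])[["S"]]
  combs <- utils::combn(10, 3)
  all_scores <- apply(combs, 2, function(idx)
    ssgsea_score(expr, genes[idx])[["S"]])
  expect_equal(max(all_scores), top)
  expect_equal(sum(all_scores >= top - 1e-12), 1L)
})

test_that("ssGSEA degenerate and symmetry behaviour", {
  genes <- paste0("g", 1:10)
  expr <- matrix(10:1, ncol = 1, dimnames = list(genes, "S"))
  expect_equal(ssgsea_score(expr, genes)[["S"]], 0)     # set covers all genes
  expect_error(ssgsea_score(expr, c("x1", "x2")), "no genes")
  expect_error(ssgsea_score(expr, c("g1", "x1", "x2", "x3")), "50%")
  # a top-half set scores positive, its complement negative
  s_top <- ssgsea_score(expr, genes[1:5])[["S"]]
  s_bot <- ssgsea_score(expr, genes[6:10])[["S"]]
  expect_gt(s_top, 0)
  expect_lt(s_bot, 0)
})

test_that("ssGSEA is invariant under monotone transforms within a sample", {
  set.seed(9)
  genes <- paste0("g", 1:50)
  expr <- matrix(rnorm(50), ncol = 1, dimnames = list(genes, "S"))
  set1 <- genes[c(2, 5, 9, 20, 33)]
  s1 <- ssgsea_score(expr, set1)[["S"]]
  expect_equal(ssgsea_score(exp(expr), set1)[["S"]], s1)
  expect_equal(ssgsea_score(expr * 100 + 7, set1)[["S"]], s1)
})

test_that("gene-set mean z matches hand-computed values and centres at zero", {
  expr <- matrix(c(1, 2, 3,
                   4, 6, 8), nrow = 2, byrow = TRUE,
                 dimnames = list(c("G1", "G2"), c("A", "B", "C")))
  z <- geneset_mean_z(expr, c("G1", "G2"))
  # per-gene z-scores: G1 (-1, 0, 1); G2 (-1, 0, 1); mean over the set
  expect_equal(unname(z), c(-1, 0, 1))
  expect_equal(mean(z), 0)
  # single-gene set equals that gene's z-score
  z1 <- geneset_mean_z(expr, "G1")
  expect_equal(unname(z1), c(-1, 0, 1))
  # constant gene dropped with a warning
  expr2 <- rbind(expr, GC = c(5, 5, 5))
  expect_warning(z2 <- geneset_mean_z(expr2, c("G1", "GC")), "constant")
  expect_equal(unname(z2), c(-1, 0, 1))
})

test_that("immune elevation in BRCA1 tumours is visible in cohort scores", {
  co <- tiny_cohort()
  im <- immune_scores(co$expression)
  gt <- co$ground_truth
  b1 <- im$immune_ssgsea[im$sample_id %in%
                           gt$sample_id[gt$carrier_group == "BRCA1"]]
  nc <- im$immune_ssgsea[im$sample_id %in%
                           gt$sample_id[gt$carrier_group == "non_carrier"]]
  expect_gt(median(b1), median(nc))
})
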