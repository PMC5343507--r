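test_that("PCA recovers rank-1 structure and reconstructs the input", {
  set.seed(4)
  u <- rnorm(30)
  v <- rnorm(8)
  m <- outer(u, v)
  p <- scanPCA(m, normalization = "per_column_center")
  # column-centered outer product is still rank 1
  expect_equal(p$varFrac[1], 1, tolerance = 1e-9)
  expect_equal(sum(p$varFrac), 1, tolerance = 1e-12)

  m2 <- matrix(rnorm(200), 20, 10)
  p2 <- scanPCA(m2)
  rec <- p2$scores %*% t(p2$loadings)
  expect_equal(rec, p2$normalized, tolerance = 1e-9,
               ignore_attr = TRUE)
  # scores of distinct components are orthogonal
  cp <- crossprod(p2$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, sum(upper.tri(cp))),
               tolerance = 1e-8)
  expect_error(scanPCA(matrix(1, 5, 5)), "constant")
})

test_that("PCA agrees with a covariance eigen-decomposition oracle", {
  set.seed(6)
  for (i in 1:20) {
    m <- matrix(rnorm(80 * 20), 80, 20)
    p <- scanPCA(m, normalization = "per_column_center")
    x <- scale(m, center = TRUE, scale = FALSE)
    ev <- eigen(stats::cov(x), symmetric = TRUE)
    expect_equal(p$varFrac, ev$values / sum(ev$values), tolerance = 1e-9)
    for (k in 1:3) {
      # same axis up to sign
      dotp <- abs(sum(p$loadings[, k] * ev$vectors[, k]))
      expect_equal(dotp, 1, tolerance = 1e-9)
      sc <- drop(x %*% ev$vectors[, k])
      expect_equal(abs(stats::cor(p$scores[, k], sc)), 1, tolerance = 1e-9)
    }
    # sign convention: non-negative loading sums
    expect_true(all(colSums(p$loadings) >= -1e-9))
  }
})

test_that("variance fractions are invariant to row order", {
  set.seed(8)
  m <- matrix(rnorm(80 * 20), 80, 20)
  p1 <- scanPCA(m)
  p2 <- scanPCA(m[sample(80), ])
  expect_equal(p1$varFrac, p2$varFrac, tolerance = 1e-9)
})

test_that("with column centering, PC1 of a row-mean-dominated matrix tracks row means", {
  set.seed(10)
  rowMeansTrue <- rnorm(80, sd = 3)          # strong per-position average
  noise <- matrix(rnorm(80 * 20, sd = 0.3), 80, 20)
  m <- rowMeansTrue + noise
  p <- scanPCA(m, normalization = "per_column_center")
  r <- pcFeatureCorrelation(p, 1, rowMeans(m))
  expect_gte(abs(r$r), 0.99)
})

test_that("per-position z-scoring standardizes rows before decomposition", {
  set.seed(12)
  m <- matrix(rnorm(200, sd = rep(c(1, 5), each = 10)), 20, 10)
  p <- scanPCA(m, normalization = "per_position_z")
  # the matrix handed to the decomposition has centered rows before column
  # centering; its row s.d.s are 1
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  expect_equal(p$normalized, scale(z, center = TRUE, scale = FALSE),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(scanPCA(rbind(m, 0), normalization = "per_position_z"),
               "constant row")
})

test_that("frequency matrices are log frequencies with no -Inf entries", {
  aa <- AA_CLASSES[-21]
  prof <- matrix(0, 20, 3, dimnames = list(aa, NULL))
  prof["A", 1] <- 1
  prof[, 2] <- 1 / 20
  prof[, 3] <- (1:20) / sum(1:20)
  msa <- simulateMsa(prof, nSequences = 5000, seed = 3)
  fm <- frequencyMatrix(msa, columns = 1:3, pseudocount = 0.01)
  expect_true(all(is.finite(fm)))
  # degenerate column: alanine near log(1), the rest near the floor
  expect_gt(fm[1, "A"], log(0.99))
  expect_true(all(fm[1, setdiff(aa, "A")] < log(0.001)))
  # uniform column: all entries equal within sampling error
  expect_lt(diff(range(fm[2, ])), 0.35)
  # monotone in true frequency
  expect_true(all(diff(fm[3, aa[order((1:20))]]) >= -0.3))
  cr <- cor(fm[3, ], log((1:20) / sum(1:20)))
  expect_gt(cr, 0.98)
  expect_error(frequencyMatrix(msa, columns = c(1, 99)), "unmapped")
})

test_that("recovered column frequencies match the generating profiles", {
  aa <- AA_CLASSES[-21]
  set.seed(5)
  prof <- matrix(rexp(20 * 4) + 0.02, 20, 4, dimnames = list(aa, NULL))
  prof <- sweep(prof, 2, colSums(prof), "/")
  n <- 5000
  msa <- simulateMsa(prof, nSequences = n, seed = 9)
  fm <- exp(frequencyMatrix(msa, columns = 1:4, pseudocount = 0))
  for (j in 1:4) {
    se <- sqrt(prof[, j] * (1 - prof[, j]) / n)
    expect_true(all(abs(fm[j, ] - prof[, j]) <= 3 * se + 1e-6))
  }
})

test_that("feature correlations report pooled and per-group values", {
  set.seed(14)
  m <- matrix(rnorm(80 * 20), 80, 20)
  p <- scanPCA(m)
  self <- pcFeatureCorrelation(p, 1, p$scores[, 1])
  expect_equal(self$r, 1, tolerance = 1e-12)
  # feature orthogonal to the scores
  f <- rnorm(80)
  f <- f - p$scores[, 1] * sum(f * p$scores[, 1]) / sum(p$scores[, 1]^2)
  orth <- pcFeatureCorrelation(p, 1, f)
  expect_equal(orth$r, 0, tolerance = 1e-9)
  grp <- rep(c("a", "b"), each = 40)
  g <- pcFeatureCorrelation(p, 1, p$scores[, 1] + rnorm(80, sd = 0.1),
                            groups = grp)
  expect_identical(names(g$byGroup), c("a", "b"))
  expect_true(all(g$byGroup > 0.9))
  expect_warning(z <- pcFeatureCorrelation(p, 1, rep(1, 80)), "zero-variance")
  expect_true(is.na(z$r))
})

test_that("four-fold averaging equals brute-force group means", {
  grid <- expand.grid(library = 1:8, withinPos = 1:10)
  # constant values stay constant
  fa <- fourfoldAverage(rep(2.5, 80), grid$library, grid$withinPos)
  expect_equal(fa$mean, rep(2.5, 20))
  # values equal to the offset reproduce the offset, self-correlation 1
  ff <- fourfoldIndex(grid$library, grid$withinPos)
  fa2 <- fourfoldAverage(ff$offset, grid$library, grid$withinPos,
                         second = ff$offset)
  expect_equal(fa2$mean, as.numeric(1:20))
  expect_equal(fa2$r, 1)
  # random values: compare against an explicit double loop
  set.seed(16)
  v <- rnorm(80)
  fa3 <- fourfoldAverage(v, grid$library, grid$withinPos)
  for (off in 1:20) {
    idx <- which(ff$offset == off)
    expect_equal(fa3$mean[off], mean(v[idx]), tolerance = 1e-12)
  }
  expect_identical(fa3$n, rep(4L, 20))
})

test_that("row-mean imputation completes excluded cells only", {
  m <- matrix(1:12, 3, 4) * 1.0
  m[2, 3] <- NA
  im <- imputeRowMean(m)
  expect_equal(im[2, 3], mean(m[2, -3]))
  expect_identical(im[-8], m[-8])  # m[2, 3] is linear index 8
  expect_error(imputeRowMean(rbind(m, NA)), "cannot be imputed")
})
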