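test_that("standardization matches robust SDS and trims at the cutoff", {
  set.seed(14)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  std <- ddc_standardize(X)
  expect_equal(std$z[, "a"], robust_sds(X[, "a"]), ignore_attr = TRUE)
  expect_equal(std$z[, "b"], robust_sds(X[, "b"]), ignore_attr = TRUE)
  # affine-transformed column yields identical z
  X2 <- X; X2[, "a"] <- 3 * X2[, "a"] - 5
  expect_equal(ddc_standardize(X2)$z, std$z)
  # a single wild cell is set aside
  X3 <- X; X3[7, "b"] <- 100
  std3 <- ddc_standardize(X3)
  expect_true(is.na(std3$z_trim[7, "b"]))
  expect_false(anyNA(std3$z[, "b"]))
  expect_error(ddc_standardize(cbind(rep(1, 10), rnorm(10))), "zero-MAD")
  expect_error(ddc_standardize(matrix(rnorm(10), ncol = 1)), "2 columns")
})

test_that("robust correlations resist single gross outliers", {
  params <- ddc_params()
  set.seed(15)
  x <- rnorm(300)
  X <- cbind(x, 2 * x)
  X[5, 2] <- 1000  # one gross outlier in an otherwise exact pair
  corr <- ddc_correlations(ddc_standardize(X, params), params)
  expect_gt(corr$corr[1, 2], 0.99)
  expect_equal(corr$corr[1, 1], 1)
  expect_equal(corr$corr, t(corr$corr))
  expect_equal(corr$connected[[1]], 2L)
  # independent columns: small correlation, columns standalone
  Y <- cbind(rnorm(1000), rnorm(1000))
  corr2 <- ddc_correlations(ddc_standardize(Y, params), params)
  expect_lt(abs(corr2$corr[1, 2]), 0.1)
  expect_length(corr2$connected[[1]], 0)
})

test_that("cell prediction follows the median-of-ratios construction", {
  params <- ddc_params()
  # exactly proportional columns: predictions equal observations for all
  # rows that survive the univariate trimming
  set.seed(16)
  x <- runif(50, -1, 1)
  X <- cbind(x, -3 * x)
  std <- ddc_standardize(X, params)
  corr <- ddc_correlations(std, params)
  pred <- ddc_predict(std, corr, params)
  keep <- !is.na(std$z_trim)
  expect_equal(pred[keep], std$z[keep], tolerance = 1e-10)

  # standalone columns are predicted as zero
  Y <- cbind(rnorm(200), rnorm(200))
  stdY <- ddc_standardize(Y, params)
  predY <- ddc_predict(stdY, ddc_correlations(stdY, params), params)
  expect_true(all(predY == 0))

  # general case: direct dense recomputation of slopes, weighting and
  # deshrinkage from the documented formulas
  set.seed(18)
  base <- rnorm(30)
  Z <- cbind(base + rnorm(30, sd = 0.3),
             -2 * base + rnorm(30, sd = 0.3),
             base + rnorm(30, sd = 0.4))
  stdZ <- ddc_standardize(Z, params)
  corrZ <- ddc_correlations(stdZ, params)
  predZ <- ddc_predict(stdZ, corrZ, params)
  zt <- stdZ$z_trim
  for (j in 1:3) {
    H <- corrZ$connected[[j]]
    if (!length(H)) next
    b <- vapply(H, function(k) {
      use <- !is.na(zt[, j]) & !is.na(zt[, k]) & abs(zt[, k]) > 1e-6
      median(zt[use, j] / zt[use, k])
    }, numeric(1))
    w <- abs(corrZ$corr[H, j])
    raw <- vapply(seq_len(30), function(i) {
      av <- !is.na(zt[i, H])
      if (!any(av)) return(0)
      sum(w[av] * b[av] * zt[i, H][av]) / sum(w[av])
    }, numeric(1))
    use <- !is.na(zt[, j]) & abs(raw) > 1e-6
    a <- median(zt[use, j] / raw[use])
    expect_equal(predZ[, j], a * raw, tolerance = 1e-12,
                 info = paste("column", j))
  }
})

test_that("cellwise flags isolate corrupted cells in linked columns", {
  params <- ddc_params()
  # bounded clean data (no marginal outliers), exact linear dependence,
  # a few corrupted cells: precision = recall = 1
  set.seed(19)
  x <- runif(400, -1, 1)
  X <- cbind(a = x, b = 2 * x)
  bad <- c(3, 50, 200)
  X[bad, "b"] <- X[bad, "b"] + 30
  fit <- ddc_fit(X, params)
  expect_equal(which(fit$cell_flags[, "b"]), bad, ignore_attr = TRUE)
  expect_false(any(fit$cell_flags[, "a"]))
  # prediction == observation implies no flags
  clean <- ddc_fit(cbind(x, 2 * x), params)
  expect_false(any(clean$cell_flags))
})

test_that("null flag rates sit near 1 - tolProb for cells and rows", {
  set.seed(23)
  n <- 3000
  base <- rnorm(n)
  X <- cbind(base + rnorm(n, sd = 0.5),
             base + rnorm(n, sd = 0.5),
             base + rnorm(n, sd = 0.5))
  fit <- ddc_fit(X)
  cell_rate <- mean(fit$cell_flags)
  expect_gt(cell_rate, 0.002)
  expect_lt(cell_rate, 0.03)
  row_rate <- mean(fit$row_flags)
  expect_lt(row_rate, 0.05)
})

test_that("the full algorithm is deterministic and affine-equivariant", {
  set.seed(25)
  base <- rnorm(150)
  X <- cbind(base + rnorm(150, sd = 0.2),
             3 * base + rnorm(150, sd = 0.5),
             -base + rnorm(150, sd = 0.3))
  X[10, 2] <- 40
  f1 <- ddc_fit(X)
  expect_identical(f1, ddc_fit(X))
  # positive affine rescaling of a column leaves the flags unchanged
  X2 <- X; X2[, 2] <- 0.25 * X2[, 2] + 100
  f2 <- ddc_fit(X2)
  expect_equal(f2$cell_flags, f1$cell_flags)
  expect_true(f1$cell_flags[10, 2])
  # rowwise statistic: bounded in [0, 1]; a fully corrupted row stands out
  # (checked on a wider matrix — with very few columns the statistic
  # saturates near 1 and its robust z-score cannot clear the cutoff)
  expect_true(all(f1$row_stat >= 0 & f1$row_stat <= 1))
  set.seed(27)
  core <- rnorm(200)
  W <- sapply(1:6, function(k) core + rnorm(200, sd = 0.4))
  W[60, ] <- W[60, ] + 25
  fw <- ddc_fit(W)
  expect_true(fw$row_flags[60])
  expect_gt(fw$row_stat[60], 0.99)
  expect_lt(mean(fw$row_flags[-60]), 0.05)
  # predicted values return to data units
  expect_equal(dim(f1$predicted), dim(X))
  expect_true(all(is.finite(f1$predicted)))
})

test_that("residual magnitude is a coherent ROC score for the flags", {
  set.seed(26)
  x <- rnorm(500)
  X <- cbind(x, 2 * x + rnorm(500, sd = 0.1))
  bad <- sample(500, 25)
  X[bad, 2] <- X[bad, 2] + 15
  fit <- ddc_fit(X)
  sc <- abs(fit$residual[, 2])
  # thresholding the score at c reproduces the cell flags exactly
  expect_equal(sc > fit$params$c, fit$cell_flags[, 2])
})
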