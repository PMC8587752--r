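test_that("PCA recovers rank-1 structure and reconstructs exactly", {
  set.seed(3)
  # rows on a line through the mean: PC1 explains everything
  dir <- rnorm(12)
  X1 <- outer(rnorm(10), dir)
  m1 <- pca_fit(X1, 1)
  expect_gt(m1$explained_fraction[1], 1 - 1e-10)

  X <- matrix(rnorm(15 * 8), 15, 8)
  m <- pca_fit(X, 8)
  Xc <- sweep(X, 2, m$column_means)
  expect_lt(max(abs(m$scores %*% t(m$loadings) - Xc)), 1e-8)
  expect_lt(max(abs(crossprod(m$loadings) - diag(8))), 1e-8)
  expect_true(all(diff(m$explained_variance) <= 1e-12))

  # permutation equivariance of scores
  perm <- sample(15)
  mp <- pca_fit(X[perm, ], 3)
  # loadings are sign-ambiguous; compare absolute scores
  expect_equal(abs(mp$scores), abs(m$scores[perm, 1:3]), tolerance = 1e-8)
})

test_that("Q residuals measure squared distance from the model plane", {
  set.seed(4)
  X <- matrix(rnorm(12 * 7), 12, 7)
  m <- pca_fit(X, 2)
  # row at the column means
  expect_lt(q_residuals(m, matrix(m$column_means, 1)), 1e-10)
  # in-span row
  r1 <- m$column_means + 5 * m$loadings[, 1]
  expect_lt(q_residuals(m, matrix(r1, 1)), 1e-10)
  # orthogonal component of norm 3
  v <- rnorm(7)
  v <- v - m$loadings %*% crossprod(m$loadings, v)
  v <- 3 * v / sqrt(sum(v^2))
  expect_lt(abs(q_residuals(m, matrix(m$column_means + v, 1)) - 9), 1e-8)
  # invariance to adding any combination of loadings
  r2 <- m$column_means + v + m$loadings %*% c(2, -7)
  expect_lt(abs(q_residuals(m, matrix(r2, 1)) - 9), 1e-8)
  expect_error(q_residuals(m, matrix(0, 1, 6)), "columns")
})

test_that("outlier flagging follows the mad and quantile rules", {
  q <- c(1, 1, 1, 1, 100)
  expect_equal(flag_outliers(q, "mad", 3.5), c(F, F, F, F, T))
  expect_equal(flag_outliers(rep(2, 6), "mad"), rep(FALSE, 6))
  expect_equal(sum(flag_outliers(as.numeric(1:100), "quantile", 0.95)), 5)
  expect_error(flag_outliers(c(-1, 2)), "nonnegative")
})

test_that("kernel PLS matches the NIPALS oracle and OLS on full rank", {
  set.seed(6)
  X <- matrix(rnorm(20 * 50), 20, 50)
  y <- drop(X %*% rnorm(50)) + rnorm(20, sd = 0.3)
  a <- 5
  fit <- pls_fit(X, y, max_factors = a, cv = NULL)
  ora <- nipals_pls1(X, y, a)
  for (k in seq_len(a)) {
    mine <- drop(sweep(X, 2, colMeans(X)) %*% fit$coefficients[, k]) +
      mean(y)
    expect_lt(max(abs(mine - ora$fitted[, k])), 1e-8)
  }
  # scores orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-6 * max(diag(G)))

  # full rank: PLS with p factors = least squares
  X2 <- matrix(rnorm(30 * 6), 30, 6)
  y2 <- drop(X2 %*% c(1, -2, 0.5, 3, 0, -1)) + rnorm(30)
  fit2 <- pls_fit(X2, y2, max_factors = 6, cv = NULL)
  ols <- stats::lm.fit(cbind(1, X2), y2)$fitted.values
  mine2 <- drop(sweep(X2, 2, colMeans(X2)) %*% fit2$coefficients[, 6]) +
    mean(y2)
  expect_lt(max(abs(mine2 - ols)), 1e-6)
})

test_that("PLS handles degenerate inputs and centering contract", {
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- rnorm(20)
  expect_error(pls_fit(X, rep(3, 20)), "constant response")
  expect_error(pls_fit(matrix(1, 20, 5), y, cv = NULL), "degenerate")
  f1 <- pls_fit(X, y, max_factors = 3, cv = NULL)
  f2 <- pls_fit(X, y + 100, max_factors = 3, cv = NULL)
  expect_equal(f2$y_predicted, f1$y_predicted + 100, tolerance = 1e-8)
})

test_that("factor selection applies the parsimony band", {
  fake <- structure(list(cv_rmse = c(5.0, 3.0, 2.9, 2.95)),
                    class = "pls_model")
  # brute-force scan of the rule
  rule <- function(cv) which(cv <= 1.02 * min(cv))[1]
  expect_equal(select_n_factors(fake), rule(fake$cv_rmse))
  expect_equal(select_n_factors(fake), 3L)
  fake$cv_rmse <- c(9, 7, 5, 3)
  expect_equal(select_n_factors(fake), 4L)
  fake$cv_rmse <- rep(2, 5)
  expect_equal(select_n_factors(fake), 1L)
})

test_that("score discrimination counts and orientation follow the score plot", {
  # perfectly separated
  d <- score_discrimination(c(1, 2, 3, -1, -2), c("o", "o", "o", "y", "y"),
                            "o")
  expect_equal(d$sensitivity, 100)
  expect_equal(d$specificity, 100)
  # 8/10 old positive, 6/8 young negative
  sc <- c(rep(1, 8), rep(-1, 2), rep(-1, 6), rep(1, 2))
  lb <- c(rep("old", 10), rep("young", 8))
  d2 <- score_discrimination(sc, lb, "old")
  expect_equal(d2$sensitivity, 80)
  expect_equal(d2$specificity, 75)
  expect_equal(c(d2$tp, d2$fn, d2$tn, d2$fp), c(8, 2, 6, 2))
  # sign invariance
  d3 <- score_discrimination(-sc, lb, "old")
  expect_equal(d3$sensitivity, d2$sensitivity)
  expect_equal(d3$specificity, d2$specificity)
  expect_true(d3$flipped)
  expect_error(score_discrimination(sc, lb, "ancient"), "nonempty")
})

test_that("pearson_r matches hand computation and rejects degeneracy", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(1:5, rep(2, 5)), "constant")
})

test_that("outlier screening removes a spiked spectrum and nothing else", {
  cfg <- small_config()
  set <- generate_cohort(cfg)
  bad <- set$spectra[[5]]
  spike <- bad$absorbance
  w <- abs(bad$wavenumbers - 2400) < 40  # artifact in a band-free window
  spike[w] <- spike[w] + 0.5
  set$spectra[[5]] <- ftir_spectrum(bad$wavenumbers, spike, bad$meta)
  # few enough components that the gross artifact is not absorbed into the
  # model subspace (single-outlier masking)
  scr <- screen_outliers(set, n_components = 3)
  expect_equal(scr$removed, names(set$spectra)[5])
  expect_equal(length(scr$kept), length(set) - 1L)
})
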