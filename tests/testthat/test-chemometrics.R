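test_that("unit-variance scaling round-trips and drops constant columns", {
  X <- cbind(a = c(1, 2, 3), b = c(2, 2, 2), c = c(0, 5, 1))
  expect_warning(Xs <- uv_scale(X), "zero-variance")
  expect_equal(colMeans(Xs), c(a = 0, c = 0))
  expect_equal(apply(Xs, 2, sd), c(a = 1, c = 1))
  expect_equal(attr(Xs, "dropped"), "b")
  back <- sweep(sweep(Xs, 2, attr(Xs, "scale"), "*"), 2, attr(Xs, "center"), "+")
  expect_equal(unclass(back)[, ], X[, c("a", "c")])
  expect_error(uv_scale(matrix(1, 3, 2)), "constant")
  expect_error(uv_scale(matrix(1, 1, 2)), "two samples")
})

test_that("PCA by SVD agrees with brute-force eigendecomposition", {
  set.seed(10)
  X <- uv_scale(matrix(rnorm(80), 10, 8))
  pc <- pca_svd(X, 3)
  ev <- eigen(crossprod(X), symmetric = TRUE)
  for (a in 1:3) {
    expect_equal(abs(sum(pc$loadings[, a] * ev$vectors[, a])), 1,
                 tolerance = 1e-8)
    expect_equal(pc$explained[a], ev$values[a] / sum(ev$values),
                 tolerance = 1e-8)
  }
  # sign convention: largest-magnitude loading positive
  for (a in 1:3)
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, a])), a], 0)
  # rank-1 matrix: first component explains everything
  r1 <- outer(rnorm(6), rnorm(4))
  pc1 <- pca_svd(r1, 1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-12)
  # reconstruction at full rank
  pcf <- pca_svd(X, min(nrow(X) - 1, ncol(X)))
  expect_equal(pcf$scores %*% t(pcf$loadings), unclass(X)[, ],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_svd(X, 99), "exceeds")
})

test_that("NIPALS PLS matches the covariance eigenstructure oracle", {
  set.seed(11)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- cbind(rnorm(12), rnorm(12))
  fit <- pls_fit(X, Y, ncomp = 1, scale = FALSE)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  S <- crossprod(Xc, Yc)
  w_oracle <- eigen(S %*% t(S), symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(sum(fit$W[, 1] * w_oracle)), 1, tolerance = 1e-8)
  # y equal to one column of an orthogonal-column design: R2 = 1 with one
  # component (the weight vector is exactly that column's axis)
  M <- matrix(rnorm(12 * 6), 12, 6)
  Xo <- qr.Q(qr(sweep(M, 2, colMeans(M))))   # orthonormal AND centered
  y <- Xo[, 3]
  fit1 <- pls_fit(Xo, y, ncomp = 1, scale = FALSE)
  expect_equal(fit1$r2[1], 1, tolerance = 1e-10)
  # joint permutation invariance of coefficients
  set.seed(12)
  perm <- sample(12)
  fit_a <- pls_fit(X, y, ncomp = 2)
  fit_b <- pls_fit(X[perm, ], y[perm], ncomp = 2)
  expect_equal(pls_coef(fit_a), pls_coef(fit_b), tolerance = 1e-10)
  # score orthogonality and non-decreasing R2
  fit2 <- pls_fit(X, Y, ncomp = 3)
  G <- crossprod(fit2$TT)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_true(all(diff(fit2$r2) >= -1e-12))
  # degenerate single-class response rejected
  expect_error(pls_fit(X, rep("a", 12), ncomp = 1), "single class")
})

test_that("segment-wise cross-validation computes honest Q2", {
  set.seed(13)
  X <- matrix(rnorm(49 * 6), 49, 6)
  y <- X %*% rnorm(6)                 # perfectly predictable
  cv <- cross_validate(X, y, folds = 7, ncomp = 6,
                       ordering = sample(49))
  expect_gt(max(cv$q2), 0.99)
  # every sample predicted exactly once
  expect_false(any(is.na(cv$pred[, , 1])))
  expect_equal(sort(unique(cv$fold)), 1:7)
  # Q2 <= R2 over random instances (randomized segment orderings)
  for (i in 1:10) {
    Xi <- matrix(rnorm(40 * 8), 40, 8)
    yi <- Xi %*% rnorm(8) * runif(1, 0.2, 1.5) + rnorm(40)
    fit <- pls_fit(Xi, yi, ncomp = 2)
    cvi <- cross_validate(Xi, yi, folds = 7, ncomp = 2, ordering = sample(40))
    expect_true(all(cvi$q2 <= fit$r2 + 1e-10))
  }
  expect_error(cross_validate(X[1:5, ], y[1:5], folds = 7), "folds")
})

test_that("Q2 is non-positive in expectation for structureless data", {
  set.seed(14)
  q2s <- replicate(60, {
    X <- matrix(rnorm(60 * 30), 60, 30)
    y <- rnorm(60)
    cross_validate(X, y, folds = 7, ncomp = 1, ordering = sample(60))$q2[1]
  })
  expect_lt(mean(q2s), 0)
})

test_that("repeated-CV misclassification counts behave at the extremes", {
  set.seed(15)
  lab <- rep(c("a", "b"), each = 30)
  # 10-sd separation in one of three variables: no misclassifications
  Xsep <- matrix(rnorm(60 * 3), 60, 3)
  Xsep[lab == "b", 1] <- Xsep[lab == "b", 1] + 10
  r <- nmc_repetitions(Xsep, lab, folds = 7, ncomp = 1, reps = 30, seed = 1)
  expect_equal(r$median, 0)
  expect_true(all(r$nmc >= 0 & r$nmc <= 60))
  # identical duplicated profiles in both classes carry no class
  # information: misclassification at (or, because cross-validated
  # prediction is anti-biased on null data, above) the chance level n/2
  Xdup <- matrix(rnorm(30 * 5), 30, 5)
  Xboth <- rbind(Xdup, Xdup)
  rdup <- nmc_repetitions(Xboth, lab, folds = 7, ncomp = 1, reps = 30, seed = 2)
  expect_gte(rdup$median, 0.4 * 60)
  # fixed seed reproduces the NMC vector exactly
  r2 <- nmc_repetitions(Xsep, lab, folds = 7, ncomp = 1, reps = 30, seed = 1)
  expect_identical(r$nmc, r2$nmc)
  expect_error(nmc_repetitions(Xsep, lab, reps = 0), "reps")
  expect_error(nmc_repetitions(Xsep, rep("a", 60), reps = 5), "classes")
})

test_that("the permutation null flags separation and respects its guards", {
  set.seed(16)
  lab <- rep(c("a", "b"), each = 15)
  X <- matrix(rnorm(30 * 4), 30, 4)
  X[lab == "b", 1] <- X[lab == "b", 1] + 8
  r <- nmc_permutation_null(X, lab, folds = 7, ncomp = 1, reps = 20,
                            nperm = 49, seed = 3)
  expect_equal(r$p_empirical, 1 / 50)     # maximal significance
  expect_lt(r$p_ranksum, 1e-10)
  expect_equal(length(r$null), 49)
  # null NMC for structureless X centers near the chance level n/2
  Xn <- matrix(rnorm(30 * 4), 30, 4)
  rn <- nmc_permutation_null(Xn, lab, folds = 7, ncomp = 1, reps = 10,
                             nperm = 49, seed = 4)
  expect_gt(median(rn$null), 9)
  expect_lt(median(rn$null), 21)
  expect_error(nmc_permutation_null(X, lab, nperm = 10), "nperm")
})

test_that("backscaled loadings have covariance amplitudes and bounded colors", {
  set.seed(17)
  X <- matrix(rnorm(8 * 5), 8, 5)
  colnames(X) <- paste0("v", 1:5)
  y <- X[, 2] + rnorm(8, 0, 0.1)
  fit <- pls_fit(X, y, ncomp = 1)
  bl <- backscale_loadings(fit, X, y = y)
  expect_true(all(abs(bl$color) <= 1))
  # first-component amplitudes proportional to the covariance of each raw
  # variable with the response (w ~ Xs'y, amplitude = w * sd)
  covs <- cov(X, y)
  expect_equal(cor(bl$amplitude, covs[, 1]), 1, tolerance = 1e-6)
  # a perfect single-variable predictor gets |color| = 1
  y2 <- 2 * X[, 4]
  fit2 <- pls_fit(X, y2, ncomp = 1)
  bl2 <- backscale_loadings(fit2, X, y = y2)
  expect_equal(abs(bl2$color[4]), 1, tolerance = 1e-12)
  # zero-sd variable contributes zero amplitude (dropped columns aside,
  # enforce via constructed sds)
  fit3 <- fit; fit3$x_scale[3] <- 0
  bl3 <- backscale_loadings(fit3, X, y = y)
  expect_equal(bl3$amplitude[3], 0)
  expect_error(backscale_loadings(fit, X[, 1:3], y = y), "mismatch")
  # rendering runs headless
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_silent(plot_backscaled_loadings(bl))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
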