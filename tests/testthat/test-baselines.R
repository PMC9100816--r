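test_that("a large enough L1 penalty zeroes every lasso coefficient", {
  set.seed(71)
  Z <- random_genotypes(40, 15)
  tr <- additive_trait(Z, n_qtl = 3, seed = 72)
  # threshold: lam*alpha > max_j |2 z_j' r| at w = 0
  Zc <- scale(Z, scale = FALSE)
  lam_max <- max(abs(2 * crossprod(Zc, tr$y)))
  fit <- enetFit(Z, tr$y, lam = lam_max * 1.01, alpha = 1)
  expect_true(all(fit$w == 0))
  # and just below the threshold at least one coefficient activates
  fit2 <- enetFit(Z, tr$y, lam = lam_max * 0.9, alpha = 1)
  expect_gt(sum(fit2$w != 0), 0)
})

test_that("lasso on an orthonormal design matches soft-thresholding", {
  set.seed(73)
  n <- 50; p <- 8
  # centered orthonormal columns (QR of a column-centered matrix), so the
  # internal centering in enetFit leaves the design unchanged
  X <- qr.Q(qr(scale(matrix(rnorm(n * p), n, p), scale = FALSE)))
  y <- rnorm(n)
  y <- y - mean(y)
  lam <- 0.8
  fit <- enetFit(X, y, lam = lam, alpha = 1, tol = 1e-12)
  ols <- as.numeric(crossprod(X, y))         # univariate OLS per column
  soft <- sign(ols) * pmax(abs(ols) - lam / 2, 0)
  expect_equal(fit$w, soft, tolerance = 1e-8)
})

test_that("ridge approaches OLS as the penalty vanishes", {
  set.seed(75)
  n <- 60; p <- 8
  Z <- random_genotypes(n, p)
  tr <- additive_trait(Z, n_qtl = 4, seed = 76)
  fit <- enetFit(Z, tr$y, lam = 1e-8, alpha = 0, tol = 1e-12)
  ols <- lm.fit(cbind(1, Z), tr$y)
  expect_equal(fit$w, unname(ols$coefficients[-1]), tolerance = 1e-4)
})

test_that("coordinate descent matches glmnet on unit-variance responses", {
  skip_if_not_installed("glmnet")
  set.seed(77)
  n <- 100; p <- 40
  Z <- random_genotypes(n, p)
  tr <- additive_trait(Z, n_qtl = 6, seed = 78)
  y <- tr$y / sqrt(mean(tr$y^2))   # unit variance so penalties align
  for (al in c(1, 0.33)) {
    lamg <- 0.05
    lams <- sort(lamg * 2^(0:8), decreasing = TRUE)
    g <- glmnet::glmnet(Z, y, alpha = al, lambda = lams, standardize = FALSE,
                        thresh = 1e-14, maxit = 1e7)
    wg <- as.numeric(glmnet::coef.glmnet(g, s = lamg, exact = TRUE,
                                         x = Z, y = y))[-1]
    mine <- enetFit(Z, y, lam = 2 * n * lamg, alpha = al, tol = 1e-12)
    expect_equal(mine$w, wg, tolerance = 1e-6)
  }
})

test_that("elastic net never does worse than the zero vector", {
  set.seed(79)
  Z <- random_genotypes(50, 20)
  tr <- additive_trait(Z, n_qtl = 5, seed = 80)
  obj <- function(w, b0, lam, alpha)
    sum((tr$y - b0 - Z %*% w)^2) +
      lam * sum((1 - alpha) / 2 * w^2 + alpha * abs(w))
  for (alpha in c(0, 0.33, 1)) {
    lam <- runif(1, 0.1, 5)
    fit <- enetFit(Z, tr$y, lam = lam, alpha = alpha)
    expect_lte(obj(fit$w, fit$intercept, lam, alpha),
               obj(numeric(20), mean(tr$y), lam, alpha) + 1e-8)
  }
})

test_that("lasso matches a slow proximal-gradient oracle", {
  set.seed(81)
  n <- 40; p <- 10
  Z <- random_genotypes(n, p)
  tr <- additive_trait(Z, n_qtl = 3, seed = 82)
  lam <- 2
  # ISTA on centered data, small constant step, many iterations
  Zc <- scale(Z, scale = FALSE)
  L <- 2 * max(eigen(crossprod(Zc), only.values = TRUE)$values)
  w <- numeric(p)
  for (it in 1:20000) {
    gsse <- -2 * as.numeric(crossprod(Zc, tr$y - Zc %*% w))
    u <- w - gsse / L
    w <- sign(u) * pmax(abs(u) - lam / L, 0)
  }
  fit <- enetFit(Z, tr$y, lam = lam, alpha = 1, tol = 1e-12)
  expect_equal(fit$w, w, tolerance = 1e-6)
})

test_that("the genomic relationship matrix has the standard properties", {
  set.seed(83)
  Z <- random_genotypes(30, 60)
  Z[2, ] <- Z[1, ]                      # duplicate individuals
  K <- grm(Z)
  expect_equal(K[1, ], K[2, ])
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, only.values = TRUE)$values), -1e-8)
  expect_error(grm(matrix(2, 10, 5)), "monomorphic")
})

test_that("GRM diagonal averages one under Hardy-Weinberg genotypes", {
  set.seed(85)
  n <- 200; p <- 1000
  maf <- runif(p, 0.05, 0.5)
  Z <- sapply(maf, function(q) rbinom(n, 2, q))
  K <- grm(Z)
  expect_equal(mean(diag(K)), 1, tolerance = 0.05)
})

test_that("heritability arithmetic", {
  expect_equal(heritability(VarianceComponents(1, 1)), 0.5)
  expect_equal(heritability(VarianceComponents(0, 1)), 0)
  expect_equal(heritability(VarianceComponents(0.7, 0.3)), 0.7)
  expect_error(VarianceComponents(0, 0), "both")
  expect_error(VarianceComponents(-1, 1), "nonnegative")
})

test_that("GBLUP recovers heritability on simulated traits", {
  h2 <- numeric(3)
  for (s in 1:3) {
    cfg <- simConfig(n = 250, p = 400, n_qtl_add = 30, h2_target = 0.5,
                     seed = 100 + s)
    Z <- simulateGenotypes(cfg)
    tr <- simulateTrait(Z, cfg)
    h2[s] <- gblupFit(Z, tr$y)$h2
  }
  expect_gt(mean(h2), 0.35)
  expect_lt(mean(h2), 0.65)
})

test_that("GBLUP h2 is near zero for pure noise and near one when noiseless", {
  set.seed(87)
  h2_null <- numeric(5)
  for (s in 1:5) {
    cfg <- simConfig(n = 300, p = 300, seed = 200 + s)
    Z <- simulateGenotypes(cfg)
    set.seed(300 + s)
    # a pure-noise trait can drive REML to the zero-variance boundary
    h2_null[s] <- suppressWarnings(gblupFit(Z, rnorm(300))$h2)
  }
  expect_lt(mean(h2_null), 0.15)

  cfg <- simConfig(n = 250, p = 300, n_qtl_add = 30, h2_target = 0.99,
                   seed = 400)
  Z <- simulateGenotypes(cfg)
  tr <- simulateTrait(Z, cfg)
  expect_gt(gblupFit(Z, tr$g)$h2, 0.9)
})

test_that("GBLUP predictions are shrunken relative to the phenotypes", {
  cfg <- simConfig(n = 200, p = 300, n_qtl_add = 20, h2_target = 0.5,
                   seed = 500)
  Z <- simulateGenotypes(cfg)
  tr <- simulateTrait(Z, cfg)
  fit <- gblupFit(Z, tr$y)
  expect_lt(var(fit$g), var(tr$y))
  # predictions for held-out individuals correlate with true genetic values
  idx <- 1:150
  pr <- gblupPredict(dosages(Z)[idx, ], tr$y[idx], dosages(Z)[-idx, ])
  expect_gt(cor(pr$pred, tr$g[-idx]), 0.2)
})
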