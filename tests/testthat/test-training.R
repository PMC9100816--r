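test_that("cosine schedule hits its endpoints and midpoint", {
  cfg <- trainConfig()
  expect_equal(cosineLR(0, cfg), 1e-3, tolerance = 1e-12)
  expect_equal(cosineLR(3000, cfg), 1e-5, tolerance = 1e-12)
  expect_equal(cosineLR(1500, cfg), (1e-3 + 1e-5) / 2, tolerance = 1e-12)
  expect_error(cosineLR(3001, cfg), "0..iterations")
  expect_error(cosineLR(-1, cfg), "0..iterations")
  # monotone decreasing along the schedule
  lrs <- cosineLR(0:3000, cfg)
  expect_true(all(diff(lrs) < 0))
})

test_that("analytic subgradient matches central finite differences", {
  set.seed(21)
  n <- 8; p <- 6; N <- 1
  act <- defaultActivations(N)
  h <- 1e-5
  checked <- 0
  while (checked < 50) {
    Z <- random_genotypes(n, p)
    par <- random_params(N, p)
    lam <- runif(1, 0.05, 1)
    # keep away from ReLU kinks and from zero parameters (subgradient kinks)
    pre_ok <- TRUE
    W <- bandWeights(par); B <- bandBiases(par)
    for (k in seq_len(2 * N + 1)) {
      off <- k - N - 1
      for (i in seq_len(p)) {
        zvals <- if (i + off >= 1 && i + off <= p) Z[, i + off] else 0
        if (any(abs(W[k, i] * zvals + B[k, i]) < 1e-3)) pre_ok <- FALSE
      }
    }
    if (!pre_ok || any(abs(W) < 1e-3) || any(abs(B) < 1e-3)) next
    y <- rnorm(n)
    g <- neuralLassoGradient(par, act, Z, y, lam)
    fd_W <- matrix(0, nrow(W), ncol(W)); fd_B <- fd_W
    for (k in seq_len(nrow(W))) for (i in seq_len(p)) {
      Wp <- W; Wm <- W
      Wp[k, i] <- W[k, i] + h; Wm[k, i] <- W[k, i] - h
      fd_W[k, i] <- (neuralLassoObjective(BandedParams(Wp, B), act, Z, y, lam) -
                     neuralLassoObjective(BandedParams(Wm, B), act, Z, y, lam)) / (2 * h)
      Bp <- B; Bm <- B
      Bp[k, i] <- B[k, i] + h; Bm[k, i] <- B[k, i] - h
      fd_B[k, i] <- (neuralLassoObjective(BandedParams(W, Bp), act, Z, y, lam) -
                     neuralLassoObjective(BandedParams(W, Bm), act, Z, y, lam)) / (2 * h)
    }
    num <- sqrt(sum((g$dW - fd_W)^2) + sum((g$dB - fd_B)^2))
    den <- sqrt(sum(fd_W^2) + sum(fd_B^2))
    expect_lt(num / den, 1e-5)
    checked <- checked + 1
  }
})

test_that("gradient is zero at a perfect fit and in ReLU dead regions", {
  set.seed(31)
  Z <- random_genotypes(10, 5)
  # perfect fit: N = 0 identity model with known weights, lam = 0
  w <- rnorm(5)
  par <- BandedParams(matrix(w, 1), matrix(0, 1, 5))
  y <- as.numeric(Z %*% w)
  g <- neuralLassoGradient(par, "identity", Z, y, 0)
  expect_lt(max(abs(g$dW)), 1e-9)
  # strictly negative pre-activations at a ReLU offset: dead, zero gradient
  par2 <- BandedParams(matrix(-1, 1, 5), matrix(-0.5, 1, 5))
  g2 <- neuralLassoGradient(par2, "relu", Z, rnorm(10), 0)
  expect_true(all(g2$dW == 0) && all(g2$dB == 0))
})

test_that("training is deterministic given the seed", {
  set.seed(41)
  Z <- random_genotypes(30, 15)
  tr <- additive_trait(Z, n_qtl = 4, seed = 42)
  cfg <- trainConfig(iterations = 100, lam = 0.5, seed = 7)
  f1 <- fitNeuralLasso(Z, tr$y, config = cfg)
  f2 <- fitNeuralLasso(Z, tr$y, config = cfg)
  expect_identical(lossTrace(f1), lossTrace(f2))
  expect_identical(bandWeights(modelParams(f1)), bandWeights(modelParams(f2)))
})

test_that("the objective decreases over training", {
  set.seed(43)
  Z <- random_genotypes(50, 20)
  tr <- additive_trait(Z, n_qtl = 5, seed = 44)
  fit <- fitNeuralLasso(Z, tr$y, config = trainConfig(iterations = 400, lam = 1))
  lt <- lossTrace(fit)
  expect_length(lt, 400)
  expect_lt(lt[length(lt)], lt[1])
})

test_that("a huge penalty collapses the parameters", {
  set.seed(45)
  Z <- random_genotypes(30, 20)
  tr <- additive_trait(Z, n_qtl = 3, seed = 46)
  cfg <- trainConfig(iterations = 500, lam = 1e6, seed = 2)
  fit <- fitNeuralLasso(Z, tr$y, config = cfg)
  init <- NeuralLasso:::init_banded_params(2, 20, cfg$init_scale, cfg$seed)
  norm_fit <- sum(abs(bandWeights(modelParams(fit)))) +
    sum(abs(bandBiases(modelParams(fit))))
  norm_init <- sum(abs(bandWeights(init))) + sum(abs(bandBiases(init)))
  expect_lt(norm_fit, 0.01 * norm_init)
})

test_that("a noiseless additive trait is recovered in-sample", {
  set.seed(47)
  Z <- random_genotypes(80, 30)
  tr <- additive_trait(Z, n_qtl = 5, noise_sd = 0, seed = 48)
  fit <- fitNeuralLasso(Z, tr$y, N = 0, act = "identity",
                        config = trainConfig(iterations = 8000, lam = 0.01))
  expect_gt(cor(predict(fit, Z), tr$y), 0.99)
})

test_that("with N=0, identity, frozen biases, fit approaches the OLS solution", {
  set.seed(49)
  n <- 60; p <- 10
  Z <- random_genotypes(n, p)
  tr <- additive_trait(Z, n_qtl = 4, noise_sd = 0.5, seed = 50)
  fit <- fitNeuralLasso(Z, tr$y, N = 0, act = "identity",
                        config = trainConfig(iterations = 6000, lam = 0,
                                             train_biases = FALSE))
  # normal-equations oracle for the same model class (no intercept,
  # y centered)
  ols <- lm.fit(Z, tr$y)
  expect_gt(cor(predict(fit, Z), ols$fitted.values), 0.999)
  expect_true(all(bandBiases(modelParams(fit)) == 0))
})

test_that("divergence is caught with the iteration named", {
  set.seed(51)
  Z <- random_genotypes(20, 10)
  y <- rnorm(20)
  expect_error(
    fitNeuralLasso(Z, y, config = trainConfig(iterations = 200,
                                              lr_start = 1e7, lr_end = 1e6)),
    "iteration")
})
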