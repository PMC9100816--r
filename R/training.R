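#' Training configuration
#'
#' Defaults follow the model's training protocol: 3000 full-batch Adam
#' iterations with a cosine learning-rate decay from 1e-3 to 1e-5.
#'
#' @param iterations number of full-batch Adam updates (default 3000).
#' @param lr_start,lr_end cosine schedule endpoints (defaults 1e-3, 1e-5;
#'   `lr_end <= lr_start`).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment decay rates and
#'   stabilizer (defaults 0.9, 0.999, 1e-8).
#' @param init_scale half-width of the uniform weight initialization
#'   (default 0.01).
#' @param seed integer RNG seed for the initialization.
#' @param lam nonnegative L1 penalty weight (default 0).
#' @param train_biases if `FALSE`, biases are fixed at zero (initialization
#'   and updates skipped), reducing the linear-activation model to a pure
#'   banded lasso (default `TRUE`).
#' @return a classed list of validated settings.
#' @export
trainConfig <- function(iterations = 3000L, lr_start = 1e-3, lr_end = 1e-5,
                        adam_beta1 = 0.9, adam_beta2 = 0.999, adam_eps = 1e-8,
                        init_scale = 0.01, seed = 1L, lam = 0,
                        train_biases = TRUE) {
  iterations <- as.integer(iterations)
  stopifnot(iterations >= 1L, lr_start > 0, lr_end > 0, lr_end <= lr_start,
            init_scale >= 0, lam >= 0)
  structure(list(iterations = iterations, lr_start = lr_start, lr_end = lr_end,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, init_scale = init_scale,
                 seed = as.integer(seed), lam = lam,
                 train_biases = isTRUE(train_biases)),
            class = "trainConfig")
}

#' Cosine learning-rate schedule
#'
#' `lr(step) = lr_end + 0.5 (lr_start - lr_end)(1 + cos(pi * step / iterations))`,
#' so `lr(0) = lr_start` and `lr(iterations) = lr_end`.
#'
#' @param step integer in `0..iterations`.
#' @param config a [trainConfig()].
#' @return the learning rate at `step`.
#' @examples
#' cosineLR(0, trainConfig())      # 1e-3
#' cosineLR(3000, trainConfig())   # 1e-5
#' @export
cosineLR <- function(step, config = trainConfig()) {
  if (any(step < 0) || any(step > config$iterations))
    stop("step must lie in 0..iterations")
  config$lr_end + 0.5 * (config$lr_start - config$lr_end) *
    (1 + cos(pi * step / config$iterations))
}

#' Subgradient of the penalized objective
#'
#' Analytic subgradient of [neuralLassoObjective()] with respect to all
#' weights and biases: the squared-error term differentiated through the
#' activations (ReLU derivative 1 for positive pre-activation, 0 otherwise,
#' including at exactly 0) plus `lam * sign(.)` on every parameter
#' (`sign(0) = 0`).
#'
#' @inheritParams neuralLassoObjective
#' @return list with matrices `dW`, `dB` mirroring the parameter layout and
#'   the `objective` value at `params`.
#' @export
neuralLassoGradient <- function(params, act, Z, y, lam) {
  stopifnot(is(params, "BandedParams"))
  Z <- as_dosage_matrix(Z)
  if (length(y) != nrow(Z))
    stop("y length must equal the number of individuals in Z")
  if (!is.numeric(lam) || lam < 0) stop("lam must be nonnegative")
  is_relu <- check_activations(act, params@neighborhood)
  g <- cpp_band_gradient(params@weights, params@biases, Z, as.numeric(y),
                         lam, is_relu)
  rn <- rownames(params@weights)
  dimnames(g$dW) <- dimnames(g$dB) <- list(rn, colnames(params@weights))
  g
}

# Seeded parameter initialization: weights ~ U(-init_scale, +init_scale),
# biases at +0.01 so ReLU offsets start in their active region (zero when
# bias training is disabled).
init_banded_params <- function(N, p, init_scale, seed, train_biases = TRUE) {
  set.seed(seed)
  W <- matrix(runif((2L * N + 1L) * p, -init_scale, init_scale), 2L * N + 1L, p)
  B <- matrix(if (train_biases) 0.01 else 0, 2L * N + 1L, p)
  BandedParams(W, B)
}

#' Fit the banded neural lasso
#'
#' Minimizes the L1-penalized squared-error objective by `iterations`
#' full-batch Adam updates with the cosine learning-rate schedule.
#' Weights are initialized i.i.d. uniform on (-init_scale, +init_scale)
#' (seeded) and biases at +0.01 so ReLU units start active. Because the L1
#' term is handled by a plain subgradient inside Adam (no proximal step),
#' fitted parameters are approximately rather than exactly sparse.
#'
#' The recorded `lossTrace` holds the objective at the parameters entering
#' each iteration, so its first element is the initial objective. Training
#' aborts with an error naming the iteration if the objective exceeds
#' 1e12 times its initial value or becomes non-finite.
#'
#' @param Z a [GenotypeMatrix-class] or numeric dosage matrix, no missing
#'   values.
#' @param y centered phenotype vector (length n).
#' @param act per-offset activations; default [defaultActivations()] for
#'   the chosen `N`.
#' @param config a [trainConfig()]; `config$lam` is the penalty weight.
#' @param N neighborhood size (default 2, a 5-locus window).
#' @return a [NeuralLassoFit-class].
#' @examples
#' set.seed(1)
#' Z <- matrix(sample(0:2, 60, TRUE), nrow = 10)
#' y <- as.numeric(scale(Z %*% rnorm(6), scale = FALSE))
#' fit <- fitNeuralLasso(Z, y, config = trainConfig(iterations = 50))
#' fit
#' @export
fitNeuralLasso <- function(Z, y, act = NULL, config = trainConfig(), N = 2L) {
  Zm <- as_dosage_matrix(Z)
  N <- as.integer(N)
  if (is.null(act)) act <- defaultActivations(N)
  is_relu <- check_activations(act, N)
  if (length(y) != nrow(Zm))
    stop("y length must equal the number of individuals in Z")
  train_biases <- !isFALSE(config$train_biases)
  p0 <- init_banded_params(N, ncol(Zm), config$init_scale, config$seed,
                           train_biases)
  res <- cpp_fit_adam(Zm, as.numeric(y), is_relu, p0@weights, p0@biases,
                      config$iterations, config$lr_start, config$lr_end,
                      config$adam_beta1, config$adam_beta2, config$adam_eps,
                      config$lam, train_biases)
  new("NeuralLassoFit",
      params = BandedParams(res$W, res$B),
      activations = act,
      lossTrace = as.numeric(res$loss_trace),
      config = unclass(config))
}

#' Predict from a fitted banded neural lasso
#'
#' @param object a [NeuralLassoFit-class].
#' @param newdata a [GenotypeMatrix-class] or dosage matrix with the same
#'   markers (columns) the model was trained on.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "NeuralLassoFit", function(object, newdata, ...) {
  bandForward(object@params, object@activations, newdata)
})
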