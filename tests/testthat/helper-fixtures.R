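# Shared fixture builders: everything is generated in code at test time.

random_genotypes <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:2, n * p, replace = TRUE), n, p)
}

random_params <- function(N, p, scale = 1) {
  BandedParams(matrix(rnorm((2 * N + 1) * p, sd = scale), 2 * N + 1, p),
               matrix(rnorm((2 * N + 1) * p, sd = scale), 2 * N + 1, p))
}

# additive trait on a plain dosage matrix: y = Z w + e, centered
additive_trait <- function(Z, n_qtl = 10, noise_sd = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(Z)
  w <- numeric(p)
  qtl <- sample(p, n_qtl)
  w[qtl] <- rnorm(n_qtl)
  y <- as.numeric(Z %*% w) + rnorm(nrow(Z), 0, noise_sd)
  list(y = y - mean(y), w = w, qtl = qtl)
}

# scalar-loop objective, independent of the package's forward code paths
objective_loop_oracle <- function(params, act, Z, y, lam) {
  N <- neighborhood(params)
  W <- bandWeights(params); B <- bandBiases(params)
  p <- ncol(Z)
  sse <- 0
  for (j in seq_len(nrow(Z))) {
    f <- 0
    for (k in seq_len(2 * N + 1)) {
      off <- k - N - 1
      for (i in seq_len(p)) {
        z <- if (i + off >= 1 && i + off <= p) Z[j, i + off] else 0
        a <- W[k, i] * z + B[k, i]
        f <- f + if (act[k] == "relu") max(a, 0) else a
      }
    }
    sse <- sse + (y[j] - f)^2
  }
  unname(sse + lam * (sum(abs(W)) + sum(abs(B))))
}
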