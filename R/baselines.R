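#' Elastic net by cyclic coordinate descent
#'
#' Minimizes
#' \deqn{\sum_i (y_i - \beta_0 - z_i'w)^2 +
#'       \lambda \sum_j [\tfrac{1-\alpha}{2} w_j^2 + \alpha |w_j|]}
#' by cyclic coordinate descent with soft-thresholding; the intercept is
#' unpenalized and handled by centering. `alpha = 1` is the lasso,
#' `alpha = 0` ridge regression. Convergence is declared when the largest
#' coefficient change in a sweep falls below `tol`.
#'
#' @param Z [GenotypeMatrix-class] or dosage matrix (no missing values).
#' @param y phenotype vector.
#' @param lam nonnegative penalty weight (on the raw sum-of-squares scale).
#' @param alpha elastic-net mixing in \[0, 1\] (default 0.33).
#' @param tol convergence tolerance on coefficient changes (default 1e-8).
#' @param max_sweeps sweep budget before an error is raised (default 10000).
#' @return list with `w` (length-p coefficients), `intercept`, `sweeps`.
#' @examples
#' Z <- matrix(sample(0:2, 200, TRUE), 20)
#' y <- Z %*% c(1, -1, rep(0, 8)) + rnorm(20, 0, 0.1)
#' enetFit(Z, y, lam = 1, alpha = 1)$w
#' @export
enetFit <- function(Z, y, lam, alpha = 0.33, tol = 1e-8, max_sweeps = 10000L) {
  Z <- as_dosage_matrix(Z)
  stopifnot(length(y) == nrow(Z), lam >= 0, alpha >= 0, alpha <= 1)
  res <- cpp_enet_cd(Z, as.numeric(y), lam, alpha, tol, as.integer(max_sweeps))
  if (!res$converged)
    stop(sprintf(paste0("coordinate descent did not converge in %d sweeps ",
                        "(lam = %g, alpha = %g); increase max_sweeps or tol"),
                 max_sweeps, lam, alpha))
  list(w = as.numeric(res$w), intercept = res$intercept, sweeps = res$sweeps)
}

#' Predict from an elastic net fit
#' @param fit result of [enetFit()].
#' @param Z genotypes to predict for.
#' @return numeric predictions.
#' @export
enetPredict <- function(fit, Z) {
  Z <- as_dosage_matrix(Z)
  as.numeric(Z %*% fit$w + fit$intercept)
}

#' Genomic relationship matrix
#'
#' VanRaden method-1 scaling: `K = Zc Zc' / d` with `Zc` the column-centered
#' dosages and `d = 2 * sum(p_k (1 - p_k))` over the observed allele
#' frequencies `p_k = colMeans(Z) / 2`. Under Hardy-Weinberg genotype
#' frequencies the diagonal of `K` averages 1.
#'
#' @param Z [GenotypeMatrix-class] or dosage matrix, complete.
#' @return symmetric positive semidefinite n x n matrix.
#' @export
grm <- function(Z) {
  Z <- as_dosage_matrix(Z)
  pk <- colMeans(Z) / 2
  d <- 2 * sum(pk * (1 - pk))
  if (d <= 0)
    stop("all markers are monomorphic; the relationship matrix is undefined")
  Zc <- sweep(Z, 2, 2 * pk)
  K <- tcrossprod(Zc) / d
  (K + t(K)) / 2
}

# Spectral REML for y = mu + g + e, g ~ N(0, sigmaG2 * K), e ~ N(0, sigmaE2 I).
# Projects out the mean, eigendecomposes the projected K and maximizes the
# restricted likelihood over delta = sigmaG2 / sigmaE2 by 1-D search on
# log(delta).
reml_spectral <- function(K, y) {
  n <- length(y)
  S <- diag(n) - matrix(1 / n, n, n)
  es <- eigen(S %*% K %*% S, symmetric = TRUE)
  keep <- seq_len(n - 1L)               # the projected space has rank n-1
  d <- pmax(es$values[keep], 0)
  eta <- as.numeric(crossprod(es$vectors[, keep, drop = FALSE], y))
  nll <- function(logdelta) {
    delta <- exp(logdelta)
    v <- delta * d + 1
    0.5 * ((n - 1) * log(sum(eta^2 / v)) + sum(log(v)))
  }
  opt <- optimize(nll, c(-12, 12))
  delta <- exp(opt$minimum)
  sigmaE2 <- sum(eta^2 / (delta * d + 1)) / (n - 1)
  sigmaG2 <- delta * sigmaE2
  boundary <- opt$minimum < -11.5 || opt$minimum > 11.5
  list(sigmaG2 = sigmaG2, sigmaE2 = sigmaE2, boundary = boundary)
}

#' GBLUP: REML variance components and genetic-value BLUPs
#'
#' Fits the random-effects model `y = mu + g + e` with
#' `g ~ N(0, sigmaG2 * K)` and `e ~ N(0, sigmaE2 * I)`, `K` the genomic
#' relationship matrix from [grm()]. Variance components are estimated by
#' restricted maximum likelihood via the eigendecomposition of the
#' mean-projected `K` and a 1-D search over the variance ratio; genetic
#' values are the BLUPs
#' `g_hat = sigmaG2 K (sigmaG2 K + sigmaE2 I)^{-1} (y - mean(y))`.
#'
#' @param Z [GenotypeMatrix-class] or dosage matrix, complete.
#' @param y phenotype vector (internally mean-centered).
#' @param K optionally a precomputed relationship matrix.
#' @return list with `vc` (a [VarianceComponents-class]), `g` (BLUP genetic
#'   values), `h2` (the heritability estimate), and `mu` (the phenotype mean).
#' @examples
#' Z <- matrix(sample(0:2, 50 * 100, TRUE), 50)
#' y <- rnorm(50)
#' gblupFit(Z, y)$h2
#' @export
gblupFit <- function(Z, y, K = NULL) {
  if (is.null(K)) K <- grm(Z)
  n <- length(y)
  stopifnot(nrow(K) == n)
  if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) < -1e-6)
    stop("relationship matrix is not positive semidefinite")
  est <- reml_spectral(K, as.numeric(y))
  if (est$boundary) {
    warning("REML solution at the boundary of the variance-ratio range")
    if (est$sigmaG2 < est$sigmaE2 * 1e-5) est$sigmaG2 <- 0
  }
  vc <- VarianceComponents(est$sigmaG2, est$sigmaE2)
  mu <- mean(y)
  V <- est$sigmaG2 * K + diag(est$sigmaE2, n)
  g <- est$sigmaG2 * (K %*% solve(V, y - mu))
  list(vc = vc, g = as.numeric(g), h2 = heritability(vc), mu = mu)
}

#' Predict genetic values for new individuals under GBLUP
#'
#' Centers both training and new dosages by the training allele frequencies,
#' builds the cross-relationship block and returns
#' `mu + sigmaG2 K_new,train (sigmaG2 K_train + sigmaE2 I)^{-1} (y - mu)`.
#'
#' @param Z_train,y_train training data used to estimate the components.
#' @param Z_new dosages of the individuals to predict.
#' @return list with `pred` (predictions for `Z_new`), `vc`, `h2`.
#' @export
gblupPredict <- function(Z_train, y_train, Z_new) {
  Zt <- as_dosage_matrix(Z_train); Zn <- as_dosage_matrix(Z_new)
  pk <- colMeans(Zt) / 2
  d <- 2 * sum(pk * (1 - pk))
  if (d <= 0) stop("all markers are monomorphic in the training set")
  Ztc <- sweep(Zt, 2, 2 * pk)
  Znc <- sweep(Zn, 2, 2 * pk)
  Kt <- tcrossprod(Ztc) / d
  Kt <- (Kt + t(Kt)) / 2
  est <- reml_spectral(Kt, as.numeric(y_train))
  mu <- mean(y_train)
  V <- est$sigmaG2 * Kt + diag(est$sigmaE2, nrow(Kt))
  a <- solve(V, y_train - mu)
  Kcross <- tcrossprod(Znc, Ztc) / d
  list(pred = as.numeric(mu + est$sigmaG2 * (Kcross %*% a)),
       vc = VarianceComponents(est$sigmaG2, est$sigmaE2),
       h2 = est$sigmaG2 / (est$sigmaG2 + est$sigmaE2))
}

#' Narrow-sense SNP heritability
#'
#' `h2 = sigmaG2 / (sigmaG2 + sigmaE2)`, the fraction of phenotypic variance
#' captured by the markers.
#'
#' @param x a [VarianceComponents-class].
#' @return heritability in \[0, 1\].
#' @examples
#' heritability(VarianceComponents(0.7, 0.3))
#' @rdname heritability
#' @export
setMethod("heritability", "VarianceComponents", function(x) {
  x@sigmaG2 / (x@sigmaG2 + x@sigmaE2)
})
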