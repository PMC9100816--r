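#' Rectified linear unit
#'
#' `relu(x) = max(x, 0)`, applied elementwise.
#'
#' @param x finite numeric vector.
#' @return `pmax(x, 0)`.
#' @examples
#' relu(c(-3, 0, 5))
#' @export
relu <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("relu() requires finite numeric input")
  pmax(x, 0)
}

#' Default per-offset activations
#'
#' The banded model thresholds the inner offsets (|offset| <= 1) with ReLU
#' and leaves the outer offsets linear, so that at the default N = 2 the
#' three central loci of each 5-locus window interact nonlinearly while the
#' outermost two enter additively.
#'
#' @param N neighborhood size.
#' @return character vector of length 2N+1 with entries `"relu"` or
#'   `"identity"`, offsets -N..N.
#' @examples
#' defaultActivations(2)
#' @export
defaultActivations <- function(N) {
  offs <- seq.int(-N, N)
  ifelse(abs(offs) <= 1L, "relu", "identity")
}

check_activations <- function(act, N) {
  if (length(act) != 2L * N + 1L)
    stop(sprintf("activations must have length 2N+1 = %d, got %d",
                 2L * N + 1L, length(act)))
  if (!all(act %in% c("relu", "identity")))
    stop("activations must be 'relu' or 'identity'")
  act == "relu"
}

# Coerce GenotypeMatrix or plain matrix to a complete numeric dosage matrix.
as_dosage_matrix <- function(Z) {
  if (is(Z, "GenotypeMatrix")) Z <- Z@dosages
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  if (anyNA(Z))
    stop("genotypes contain missing values; run qcFilter() to drop or ",
         "mean-impute them before modeling")
  Z
}

#' Banded neural forward map
#'
#' Computes the model prediction for every individual: for individual j,
#' \deqn{\Lambda(z_j) = \sum_{n=-N}^{N} \sum_{i=1}^{p}
#'       \phi_n(c_{n,i}\, z_{j,i+n} + b_{n,i}),}
#' where \eqn{z_{j,i+n}} is taken as 0 when \eqn{i+n} falls outside 1..p
#' (zero-padded boundary) while the bias term is still added and passed
#' through the offset's activation \eqn{\phi_n}.
#'
#' @param params a [BandedParams-class].
#' @param act per-offset activations (see [defaultActivations()]).
#' @param Z a [GenotypeMatrix-class] or numeric matrix (individuals x
#'   markers) without missing values.
#' @return numeric vector of n predictions.
#' @examples
#' Z <- matrix(c(2, 1), nrow = 1)
#' par <- BandedParams(matrix(c(1, -1), 1), matrix(c(0, 0.5), 1))
#' bandForward(par, "relu", Z)  # ReLU(2) + ReLU(-0.5) = 2
#' @export
bandForward <- function(params, act, Z) {
  stopifnot(is(params, "BandedParams"))
  Z <- as_dosage_matrix(Z)
  N <- params@neighborhood
  if (ncol(params@weights) != ncol(Z))
    stop(sprintf("params are for p = %d markers but Z has p = %d",
                 ncol(params@weights), ncol(Z)))
  is_relu <- check_activations(act, N)
  as.numeric(cpp_band_forward(params@weights, params@biases, Z, is_relu))
}

#' Reference forward map (explicit triple loop)
#'
#' Computes the same quantity as [bandForward()] by an explicit
#' per-individual, per-locus, per-offset loop with no vectorized shortcuts.
#' Kept as an independent reference implementation; the two agree to
#' floating-point tolerance on any valid input.
#'
#' @inheritParams bandForward
#' @return numeric vector of n predictions.
#' @export
denseForwardOracle <- function(params, act, Z) {
  stopifnot(is(params, "BandedParams"))
  Z <- as_dosage_matrix(Z)
  N <- params@neighborhood
  if (ncol(params@weights) != ncol(Z))
    stop("dimension mismatch between params and Z")
  check_activations(act, N)
  n <- nrow(Z); p <- ncol(Z)
  out <- numeric(n)
  for (j in seq_len(n)) {
    acc <- 0
    for (k in seq_len(2L * N + 1L)) {
      off <- k - N - 1L
      phi <- act[k]
      for (i in seq_len(p)) {
        zi <- if (i + off >= 1L && i + off <= p) Z[j, i + off] else 0
        a <- params@weights[k, i] * zi + params@biases[k, i]
        acc <- acc + if (phi == "relu") max(a, 0) else a
      }
    }
    out[j] <- acc
  }
  out
}

#' L1 penalty on all banded parameters
#'
#' `lam * (sum(|weights|) + sum(|biases|))`.
#'
#' @param params a [BandedParams-class].
#' @param lam nonnegative penalty weight.
#' @return the penalty value.
#' @export
l1Penalty <- function(params, lam) {
  stopifnot(is(params, "BandedParams"))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single nonnegative number")
  lam * (sum(abs(params@weights)) + sum(abs(params@biases)))
}

#' Penalized training objective
#'
#' Sum of squared prediction errors plus the L1 penalty:
#' \eqn{\sum_j (y_j - \Lambda(z_j))^2 + \lambda \sum (|c| + |b|)}.
#'
#' @inheritParams bandForward
#' @param y numeric phenotype vector (length n).
#' @param lam nonnegative penalty weight.
#' @return the objective value.
#' @export
neuralLassoObjective <- function(params, act, Z, y, lam) {
  f <- bandForward(params, act, Z)
  if (length(y) != length(f))
    stop("y length must equal the number of individuals in Z")
  sum((y - f)^2) + l1Penalty(params, lam)
}
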