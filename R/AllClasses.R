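#' GenotypeMatrix: genome-ordered SNP dosages
#'
#' Container for an n individuals x p markers matrix of allele dosages
#' (counts of one allele, 0/1/2), together with marker identifiers and
#' genome coordinates. Column order is genomic order: adjacent columns are
#' adjacent loci, and that adjacency defines the neighborhoods the banded
#' model operates on.
#'
#' Entries may be `NA` before QC; [qcFilter()] removes or mean-imputes them
#' (imputed dosages are fractional, hence validity only requires values in
#' \[0, 2\]). [readGenotypes()] enforces the strict 0/1/2/NA coding on input.
#'
#' @slot dosages numeric matrix, n x p, values in \[0, 2\] or NA.
#' @slot markerIds character vector of p marker names.
#' @slot positions numeric vector of p coordinates, nondecreasing within
#'   each chromosome.
#' @slot chromosome character vector of p chromosome labels.
#'
#' @aliases GenotypeMatrix-class
#' @export
setClass("GenotypeMatrix",
  representation(
    dosages    = "matrix",
    markerIds  = "character",
    positions  = "numeric",
    chromosome = "character"
  )
)

setValidity("GenotypeMatrix", function(object) {
  Z <- object@dosages
  p <- ncol(Z)
  msgs <- character()
  if (!is.numeric(Z))
    msgs <- c(msgs, "dosages must be a numeric matrix")
  v <- Z[!is.na(Z)]
  if (length(v) && (min(v) < 0 || max(v) > 2))
    msgs <- c(msgs, "dosages must lie in [0, 2] (allele counts)")
  if (length(object@markerIds) != p)
    msgs <- c(msgs, "markerIds length must equal the number of markers")
  if (length(object@positions) != p)
    msgs <- c(msgs, "positions length must equal the number of markers")
  if (length(object@chromosome) != p)
    msgs <- c(msgs, "chromosome length must equal the number of markers")
  for (chr in unique(object@chromosome)) {
    pos <- object@positions[object@chromosome == chr]
    if (is.unsorted(pos))
      msgs <- c(msgs, sprintf("positions must be nondecreasing within chromosome %s", chr))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix of allele dosages, individuals in rows,
#'   markers in columns (genomic order).
#' @param markerIds marker names; defaults to column names or `m1..mp`.
#' @param positions genome coordinates per marker; defaults to `1:p`.
#' @param chromosome chromosome label per marker; defaults to `"1"`.
#' @return A [GenotypeMatrix-class] object.
#' @examples
#' Z <- GenotypeMatrix(matrix(c(0, 1, 2, 2, 1, 0), nrow = 3))
#' dim(Z)
#' @export
GenotypeMatrix <- function(dosages, markerIds = NULL, positions = NULL,
                           chromosome = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  p <- ncol(dosages)
  if (is.null(markerIds))
    markerIds <- if (!is.null(colnames(dosages))) colnames(dosages)
                 else paste0("m", seq_len(p))
  if (is.null(positions)) positions <- as.numeric(seq_len(p))
  if (is.null(chromosome)) chromosome <- rep("1", p)
  if (length(chromosome) == 1L) chromosome <- rep(chromosome, p)
  if (length(markerIds) == p) colnames(dosages) <- markerIds
  new("GenotypeMatrix", dosages = dosages, markerIds = as.character(markerIds),
      positions = as.numeric(positions), chromosome = as.character(chromosome))
}

#' BandedParams: per-offset weights and biases of the banded model
#'
#' The banded linear operator is held as 2N+1 weight vectors and 2N+1 bias
#' vectors of length p, one pair per diagonal offset -N..N (rows of the
#' `weights`/`biases` matrices, in offset order). Its dense realization
#' ([denseWeights()]) is a p x p band matrix with bandwidth N.
#'
#' @slot neighborhood integer N >= 0, number of sub/superdiagonals per side.
#' @slot weights numeric matrix, (2N+1) x p; row k holds the weight vector
#'   for offset k - N - 1.
#' @slot biases numeric matrix, same shape as `weights`.
#'
#' @aliases BandedParams-class
#' @export
setClass("BandedParams",
  representation(
    neighborhood = "integer",
    weights      = "matrix",
    biases       = "matrix"
  )
)

setValidity("BandedParams", function(object) {
  N <- object@neighborhood
  msgs <- character()
  if (length(N) != 1L || is.na(N) || N < 0L)
    msgs <- c(msgs, "neighborhood must be a single nonnegative integer")
  if (nrow(object@weights) != 2L * N + 1L)
    msgs <- c(msgs, "weights must have exactly 2N+1 rows (one per offset)")
  if (!identical(dim(object@weights), dim(object@biases)))
    msgs <- c(msgs, "weights and biases must have identical dimensions")
  if (anyNA(object@weights) || anyNA(object@biases))
    msgs <- c(msgs, "weights and biases must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct BandedParams
#'
#' @param weights (2N+1) x p matrix of per-offset weight vectors, offsets
#'   -N..N in row order.
#' @param biases matrix of the same shape with per-offset bias vectors.
#' @return A [BandedParams-class] object.
#' @examples
#' par <- BandedParams(matrix(0, 5, 10), matrix(0, 5, 10))  # N = 2, p = 10
#' neighborhood(par)
#' @export
BandedParams <- function(weights, biases) {
  weights <- as.matrix(weights); biases <- as.matrix(biases)
  storage.mode(weights) <- "double"; storage.mode(biases) <- "double"
  if (nrow(weights) %% 2L == 0L)
    stop("weights must have an odd number of rows (2N+1 offsets)")
  N <- (nrow(weights) - 1L) %/% 2L
  offs <- as.character(seq.int(-N, N))
  rownames(weights) <- offs; rownames(biases) <- offs
  new("BandedParams", neighborhood = as.integer(N),
      weights = weights, biases = biases)
}

#' Zero-initialized BandedParams
#'
#' @param N neighborhood size (sub/superdiagonals per side).
#' @param p number of markers.
#' @return A [BandedParams-class] object with all weights and biases zero.
#' @export
zeroBandedParams <- function(N, p) {
  BandedParams(matrix(0, 2L * N + 1L, p), matrix(0, 2L * N + 1L, p))
}

#' NeuralLassoFit: a fitted banded neural lasso model
#'
#' @slot params fitted [BandedParams-class].
#' @slot activations per-offset activation tags ("relu"/"identity").
#' @slot lossTrace objective value at the parameters entering each Adam
#'   iteration; element 1 is the initial objective.
#' @slot config the [trainConfig()] used.
#'
#' @aliases NeuralLassoFit-class
#' @export
setClass("NeuralLassoFit",
  representation(
    params      = "BandedParams",
    activations = "character",
    lossTrace   = "numeric",
    config      = "list"
  )
)

#' VarianceComponents: genomic and residual variances
#'
#' @slot sigmaG2 genomic variance (trait units squared).
#' @slot sigmaE2 residual variance (trait units squared).
#' @aliases VarianceComponents-class
#' @export
setClass("VarianceComponents",
  representation(sigmaG2 = "numeric", sigmaE2 = "numeric")
)

setValidity("VarianceComponents", function(object) {
  msgs <- character()
  if (object@sigmaG2 < 0 || object@sigmaE2 < 0)
    msgs <- c(msgs, "variance components must be nonnegative")
  if (object@sigmaG2 == 0 && object@sigmaE2 == 0)
    msgs <- c(msgs, "variance components must not both be zero")
  if (length(msgs)) msgs else TRUE
})

#' Construct VarianceComponents
#' @param sigmaG2 genomic variance.
#' @param sigmaE2 residual variance.
#' @return A [VarianceComponents-class] object.
#' @export
VarianceComponents <- function(sigmaG2, sigmaE2) {
  new("VarianceComponents", sigmaG2 = as.numeric(sigmaG2),
      sigmaE2 = as.numeric(sigmaE2))
}

#' CVReport: repeated k-fold cross-validation accuracies for one method
#'
#' @slot method method label.
#' @slot accuracies data.frame with columns `rep`, `fold`, `accuracy`
#'   (Pearson correlation on the held-out fold).
#' @slot meanAccuracy arithmetic mean of all fold accuracies.
#' @slot scheme the [cvScheme()] used.
#' @slot provenance list recording tuning choices (e.g. the lambda used).
#' @aliases CVReport-class
#' @export
setClass("CVReport",
  representation(
    method       = "character",
    accuracies   = "data.frame",
    meanAccuracy = "numeric",
    scheme       = "list",
    provenance   = "list"
  )
)

setValidity("CVReport", function(object) {
  msgs <- character()
  if (!all(c("rep", "fold", "accuracy") %in% names(object@accuracies)))
    msgs <- c(msgs, "accuracies must have columns rep, fold, accuracy")
  m <- mean(object@accuracies$accuracy)
  if (is.finite(m) && abs(m - object@meanAccuracy) > 1e-12)
    msgs <- c(msgs, "meanAccuracy must equal the mean of the fold accuracies")
  if (length(msgs)) msgs else TRUE
})
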