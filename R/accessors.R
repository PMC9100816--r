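#' Accessors for GenotypeMatrix
#'
#' `dosages()` returns the n x p dosage matrix, `markerIds()`, `positions()`
#' and `chromosome()` the per-marker metadata. `dim()` follows the matrix.
#'
#' @param x a [GenotypeMatrix-class].
#' @return the corresponding slot.
#' @name dosages
NULL

#' @rdname dosages
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname dosages
#' @export
setMethod("markerIds", "GenotypeMatrix", function(x) x@markerIds)

#' @rdname dosages
#' @export
setMethod("positions", "GenotypeMatrix", function(x) x@positions)

#' @rdname dosages
#' @export
setMethod("chromosome", "GenotypeMatrix", function(x) x@chromosome)

#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosages))

#' Subset a GenotypeMatrix
#'
#' `x[i, j]` subsets individuals (rows) and/or markers (columns), keeping
#' the marker metadata in step.
#'
#' @param x a [GenotypeMatrix-class].
#' @param i individual (row) index.
#' @param j marker (column) index.
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeMatrix.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  new("GenotypeMatrix",
      dosages    = x@dosages[i, j, drop = FALSE],
      markerIds  = x@markerIds[j],
      positions  = x@positions[j],
      chromosome = x@chromosome[j])
})

setMethod("show", "GenotypeMatrix", function(object) {
  d <- dim(object@dosages)
  nmiss <- sum(is.na(object@dosages))
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers\n", d[1], d[2]))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(object@chromosome), collapse = ", ")))
  cat(sprintf("  missing entries: %d (%.2f%%)\n", nmiss,
              100 * nmiss / max(1, prod(d))))
})

#' Accessors for BandedParams
#'
#' `neighborhood()` returns N, `bandWeights()`/`bandBiases()` the
#' (2N+1) x p per-offset parameter matrices (offsets -N..N in row order),
#' and `denseWeights()` the dense p x p realization of the band: entry
#' (i, i+n) equals the offset-n weight at locus i, all entries with
#' |row - col| > N are zero.
#'
#' @param x a [BandedParams-class].
#' @return see the description of each accessor.
#' @name bandedAccessors
NULL

#' @rdname bandedAccessors
#' @export
setMethod("neighborhood", "BandedParams", function(x) x@neighborhood)

#' @rdname bandedAccessors
#' @export
setMethod("bandWeights", "BandedParams", function(x) x@weights)

#' @rdname bandedAccessors
#' @export
setMethod("bandBiases", "BandedParams", function(x) x@biases)

#' @rdname bandedAccessors
#' @export
setMethod("denseWeights", "BandedParams", function(x) {
  N <- x@neighborhood
  p <- ncol(x@weights)
  C <- matrix(0, p, p)
  for (k in seq_len(2L * N + 1L)) {
    off <- k - N - 1L
    for (i in seq_len(p)) {
      j <- i + off
      if (j >= 1L && j <= p) C[i, j] <- x@weights[k, i]
    }
  }
  C
})

setMethod("show", "BandedParams", function(object) {
  cat(sprintf("BandedParams: N = %d (%d offsets), p = %d markers\n",
              object@neighborhood, nrow(object@weights), ncol(object@weights)))
  cat(sprintf("  sum |weights| = %.4g, sum |biases| = %.4g\n",
              sum(abs(object@weights)), sum(abs(object@biases))))
})

#' Accessors for NeuralLassoFit
#'
#' `modelParams()` returns the fitted [BandedParams-class], `lossTrace()`
#' the per-iteration objective values (element 1 is the initial objective).
#'
#' @param x a [NeuralLassoFit-class].
#' @return see description.
#' @name fitAccessors
NULL

#' @rdname fitAccessors
#' @export
setMethod("modelParams", "NeuralLassoFit", function(x) x@params)

#' @rdname fitAccessors
#' @export
setMethod("lossTrace", "NeuralLassoFit", function(x) x@lossTrace)

setMethod("show", "NeuralLassoFit", function(object) {
  cat(sprintf("NeuralLassoFit: N = %d, p = %d, lambda = %.4g\n",
              object@params@neighborhood, ncol(object@params@weights),
              object@config$lam))
  cat(sprintf("  activations: %s\n", paste(object@activations, collapse = " ")))
  cat(sprintf("  objective: %.6g (initial) -> %.6g (final), %d iterations\n",
              object@lossTrace[1], object@lossTrace[length(object@lossTrace)],
              length(object@lossTrace)))
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf("VarianceComponents: sigma_g^2 = %.4g, sigma_e^2 = %.4g (h2 = %.3f)\n",
              object@sigmaG2, object@sigmaE2,
              object@sigmaG2 / (object@sigmaG2 + object@sigmaE2)))
})

#' Accessors for CVReport
#'
#' `accuracies()` returns the per-repeat, per-fold accuracy table;
#' `meanAccuracy()` the arithmetic mean over all folds and repeats.
#'
#' @param x a [CVReport-class].
#' @return see description.
#' @name cvAccessors
NULL

#' @rdname cvAccessors
#' @export
setMethod("meanAccuracy", "CVReport", function(x) x@meanAccuracy)

#' @rdname cvAccessors
#' @export
setMethod("accuracies", "CVReport", function(x) x@accuracies)

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %s\n", object@method))
  cat(sprintf("  %d repeats x %d folds; mean Pearson accuracy = %.4f (sd %.4f)\n",
              length(unique(object@accuracies$rep)),
              length(unique(object@accuracies$fold)),
              object@meanAccuracy, sd(object@accuracies$accuracy)))
})
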