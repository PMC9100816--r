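#' Cross-validation scheme
#'
#' Defaults reproduce the evaluation protocol: 5 folds (80/20 splits),
#' 50 repeats, mean Pearson accuracy.
#'
#' @param k number of folds (default 5).
#' @param repeats number of repeated random partitions (default 50).
#' @param seed RNG seed for the partitions.
#' @return a classed list of validated settings.
#' @export
cvScheme <- function(k = 5L, repeats = 50L, seed = 1L) {
  k <- as.integer(k); repeats <- as.integer(repeats)
  stopifnot(k >= 2L, repeats >= 1L)
  structure(list(k = k, repeats = repeats, seed = as.integer(seed)),
            class = "cvScheme")
}

#' Repeated k-fold splits
#'
#' For each repeat, a seeded random permutation of `1:n` is partitioned into
#' `k` folds whose sizes differ by at most 1; each fold serves once as the
#' validation set. Identical `(n, scheme)` give identical splits, so methods
#' compared in one run can reuse the same partitions.
#'
#' @param n number of individuals.
#' @param scheme a [cvScheme()].
#' @return list of length `repeats * k`; each element is a list with
#'   `train`, `val` index vectors and the `rep`/`fold` labels.
#' @examples
#' sp <- kfoldSplits(10, cvScheme(k = 5, repeats = 1))
#' lengths(lapply(sp, `[[`, "val"))
#' @export
kfoldSplits <- function(n, scheme = cvScheme()) {
  if (n < scheme$k) stop("n must be at least the number of folds")
  set.seed(scheme$seed)
  out <- list()
  sizes <- rep(n %/% scheme$k, scheme$k) +
    as.integer(seq_len(scheme$k) <= n %% scheme$k)
  for (r in seq_len(scheme$repeats)) {
    perm <- sample.int(n)
    stops <- cumsum(sizes)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (f in seq_len(scheme$k)) {
      val <- sort(perm[starts[f]:stops[f]])
      out[[length(out) + 1L]] <- list(rep = r, fold = f, val = val,
                                      train = setdiff(seq_len(n), val))
    }
  }
  out
}

#' Pearson prediction accuracy
#'
#' Sample Pearson correlation between predicted and observed phenotypes —
#' the standard accuracy measure in genomic prediction.
#'
#' @param y_hat predictions.
#' @param y observations (same length, >= 2).
#' @return correlation in \[-1, 1\].
#' @export
pearsonAccuracy <- function(y_hat, y) {
  if (length(y_hat) != length(y) || length(y) < 2L)
    stop("y_hat and y must have equal length >= 2")
  if (sd(y_hat) == 0 || sd(y) == 0)
    stop("zero variance in predictions or observations; ",
         "correlation is undefined")
  cor(y_hat, y)
}

#' Repeated cross-validated accuracy of a prediction method
#'
#' For every fold of every repeat: fits on the training individuals
#' (phenotypes centered by the training-fold mean only), predicts the
#' validation individuals, and records the Pearson accuracy. Pass the same
#' `splits` to evaluate several methods on identical partitions. A fold with
#' constant predictions (e.g. a fully shrunk penalized fit) records accuracy
#' 0 with a warning rather than failing the whole run.
#'
#' @param fit_fn function(Z_train, y_train) -> model object.
#' @param predict_fn function(model, Z_val) -> numeric predictions.
#' @param Z [GenotypeMatrix-class] or dosage matrix.
#' @param y phenotype vector.
#' @param scheme a [cvScheme()].
#' @param method label recorded in the report.
#' @param splits optional precomputed [kfoldSplits()] (shared across
#'   methods); defaults to `kfoldSplits(nrow(Z), scheme)`.
#' @param provenance optional list recording tuning choices.
#' @return a [CVReport-class].
#' @export
evaluateMethod <- function(fit_fn, predict_fn, Z, y, scheme = cvScheme(),
                           method = "method", splits = NULL,
                           provenance = list()) {
  Zm <- as_dosage_matrix(Z)
  stopifnot(length(y) == nrow(Zm))
  if (is.null(splits)) splits <- kfoldSplits(nrow(Zm), scheme)
  rows <- lapply(splits, function(sp) {
    y_tr <- y[sp$train]
    mu <- mean(y_tr)
    model <- tryCatch(
      fit_fn(Zm[sp$train, , drop = FALSE], y_tr - mu),
      error = function(e) stop(sprintf("fit failed in repeat %d fold %d: %s",
                                       sp$rep, sp$fold, conditionMessage(e))))
    pred <- predict_fn(model, Zm[sp$val, , drop = FALSE]) + mu
    acc <- if (sd(pred) == 0 || sd(y[sp$val]) == 0) {
      warning(sprintf(paste0("constant predictions or phenotypes in repeat ",
                             "%d fold %d; accuracy recorded as 0"),
                      sp$rep, sp$fold))
      0
    } else {
      pearsonAccuracy(pred, y[sp$val])
    }
    data.frame(rep = sp$rep, fold = sp$fold, accuracy = acc)
  })
  tab <- do.call(rbind, rows)
  new("CVReport", method = method, accuracies = tab,
      meanAccuracy = mean(tab$accuracy), scheme = unclass(scheme),
      provenance = provenance)
}

#' Join CV reports into a comparison table
#'
#' One row per method with its mean accuracy and, when a reference method is
#' given, the percent difference `100 * (r_method - r_ref) / r_ref`.
#'
#' @param reports list of [CVReport-class] objects.
#' @param reference optional method label to compute percent differences
#'   against.
#' @return data.frame with columns `method`, `mean_accuracy`, `sd_accuracy`
#'   and (with a reference) `pct_vs_ref`.
#' @export
compareReports <- function(reports, reference = NULL) {
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(method = r@method, mean_accuracy = r@meanAccuracy,
               sd_accuracy = sd(r@accuracies$accuracy))
  }))
  if (!is.null(reference)) {
    if (!reference %in% tab$method)
      stop(sprintf("reference method '%s' not among the reports", reference))
    r_ref <- tab$mean_accuracy[tab$method == reference]
    tab$pct_vs_ref <- 100 * (tab$mean_accuracy - r_ref) / r_ref
  }
  tab
}
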