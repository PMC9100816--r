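#' Configuration of the bisection search for the penalty weight
#'
#' @param interval_low,interval_high nonnegative interval endpoints for
#'   lambda with `interval_low < interval_high` (defaults 1e-3 and 1e2).
#' @param max_steps maximum bisection steps (default 10).
#' @param min_width stop once the interval is narrower than this
#'   (default 1e-4).
#' @param log_scale if `TRUE`, bisect on log10(lambda) instead of the
#'   linear scale (default `FALSE`).
#' @return a classed list of validated settings.
#' @export
lambdaSearchConfig <- function(interval_low = 1e-3, interval_high = 1e2,
                               max_steps = 10L, min_width = 1e-4,
                               log_scale = FALSE) {
  stopifnot(interval_low >= 0, interval_low < interval_high, max_steps >= 1,
            min_width > 0)
  structure(list(interval_low = interval_low, interval_high = interval_high,
                 max_steps = as.integer(max_steps), min_width = min_width,
                 log_scale = isTRUE(log_scale)),
            class = "lambdaSearchConfig")
}

#' Validation-split score of a penalty weight
#'
#' Fits the banded neural lasso on the training split at penalty `lam` and
#' returns the Pearson correlation between predicted and observed phenotypes
#' on the validation split. If the validation predictions are (numerically)
#' constant — typical of a penalty-dominated fit — the score is defined as 0
#' with a warning.
#'
#' @param lam penalty weight.
#' @param Z_train,y_train training genotypes/phenotypes.
#' @param Z_val,y_val validation genotypes/phenotypes (disjoint individuals).
#' @param act per-offset activations (default from `N`).
#' @param config a [trainConfig()] (its `lam` is overridden by `lam`).
#' @param N neighborhood size.
#' @return Pearson correlation in \[-1, 1\], or 0 for degenerate predictions.
#' @export
validationScore <- function(lam, Z_train, y_train, Z_val, y_val,
                            act = NULL, config = trainConfig(), N = 2L) {
  config$lam <- lam
  fit <- fitNeuralLasso(Z_train, y_train, act = act, config = config, N = N)
  pred <- predict(fit, Z_val)
  if (sd(pred) < 1e-12 || sd(y_val) < 1e-12) {
    warning("constant predictions on the validation split; score set to 0")
    return(0)
  }
  cor(pred, y_val)
}

#' Tune the penalty weight by modified bisection
#'
#' Searches for the lambda with the best validation score on a single
#' train/validation split, by a modified bisection: the score is evaluated
#' at the interval endpoints a, b and the midpoint (a+b)/2; if an endpoint
#' scores best the interval is shifted (same width) so that endpoint becomes
#' the new midpoint (one new evaluation); if the midpoint scores best the
#' interval is halved around it (two new evaluations). On exact ties the
#' midpoint wins (halving, which guarantees termination). Shifted intervals
#' are clipped at 0 from below. The search stops after `max_steps` steps or
#' when the interval is narrower than `min_width`, and always returns the
#' best lambda among all evaluated points.
#'
#' @param config a [lambdaSearchConfig()].
#' @param score_fn function(lambda) -> score; typically a closure around
#'   [validationScore()]. Larger is better.
#' @return list with `best_lam`, `best_score`, a data.frame `trace` of all
#'   `(lam, score)` evaluations in order, `n_evals`, and the final
#'   `interval` (with its `width`) on the raw lambda scale. The best
#'   observed lambda always lies within one final-interval width of the
#'   maximizer of a unimodal score surface.
#' @examples
#' res <- tuneLambda(lambdaSearchConfig(0, 10), function(l) -(l - 3)^2)
#' res$best_lam
#' @export
tuneLambda <- function(config, score_fn) {
  stopifnot(inherits(config, "lambdaSearchConfig"), is.function(score_fn))
  to_raw <- if (config$log_scale) function(x) 10^x else identity
  a <- config$interval_low; b <- config$interval_high
  if (config$log_scale) { a <- log10(max(a, 1e-12)); b <- log10(b) }
  cache <- new.env(parent = emptyenv())
  trace <- list()
  eval_pt <- function(x) {
    key <- sprintf("%.17g", x)
    if (!is.null(cache[[key]])) return(cache[[key]])
    s <- score_fn(to_raw(x))
    cache[[key]] <- s
    trace[[length(trace) + 1L]] <<- c(lam = to_raw(x), score = s)
    s
  }
  mid <- (a + b) / 2
  sa <- eval_pt(a); sb <- eval_pt(b); sm <- eval_pt(mid)
  for (step in seq_len(config$max_steps)) {
    w <- b - a
    if (w < config$min_width) break
    # midpoint wins ties
    if (sm >= sa && sm >= sb) {          # halve around the midpoint
      a <- mid - w / 4; b <- mid + w / 4
      if (!config$log_scale) a <- max(0, a)
      sa <- eval_pt(a); sb <- eval_pt(b)
    } else if (sa > sb) {                # shift left around a
      b <- mid; sb <- sm
      mid <- a; sm <- sa
      a <- if (config$log_scale) a - w / 2 else max(0, a - w / 2)
      sa <- eval_pt(a)
      next
    } else {                             # shift right around b
      a <- mid; sa <- sm
      mid <- b; sm <- sb
      b <- b + w / 2
      sb <- eval_pt(b)
      next
    }
    mid <- (a + b) / 2
    sm <- eval_pt(mid)
  }
  tr <- as.data.frame(do.call(rbind, trace))
  best <- which.max(tr$score)
  iv <- sort(c(to_raw(a), to_raw(b)))
  list(best_lam = tr$lam[best], best_score = tr$score[best],
       trace = tr, n_evals = nrow(tr),
       interval = iv, width = diff(iv))
}
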