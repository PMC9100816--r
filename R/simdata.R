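#' Simulation configuration
#'
#' Settings for the synthetic genotype/trait generator: biallelic dosages
#' with per-marker minor-allele frequencies, local linkage disequilibrium
#' from an AR(1) latent haplotype process, and traits combining additive
#' effects with neighboring-marker epistatic interactions at a target
#' narrow-sense heritability.
#'
#' @param n individuals.
#' @param p markers.
#' @param maf_range minor-allele-frequency interval within (0, 0.5\]
#'   (default c(0.1, 0.5)).
#' @param ld_rho adjacent-marker latent correlation in \[0, 1) (default 0.5).
#' @param n_qtl_add number of additive QTL (default 20).
#' @param n_qtl_epi number of epistatic locus pairs (default 10).
#' @param epi_window maximum distance (in loci) between interacting pair
#'   members, default 2 so every pair lies inside a 5-locus window.
#' @param epi_var_frac fraction of genetic variance from epistasis in
#'   \[0, 1\] (default 0).
#' @param h2_target narrow-sense heritability target in (0, 1)
#'   (default 0.5).
#' @param seed RNG seed.
#' @return a classed list of validated settings.
#' @export
simConfig <- function(n = 500L, p = 1000L, maf_range = c(0.1, 0.5),
                      ld_rho = 0.5, n_qtl_add = 20L, n_qtl_epi = 10L,
                      epi_window = 2L, epi_var_frac = 0, h2_target = 0.5,
                      seed = 1L) {
  stopifnot(n >= 2, p >= 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1,
            n_qtl_add <= p, n_qtl_epi <= p, epi_window >= 1,
            epi_var_frac >= 0, epi_var_frac <= 1,
            h2_target > 0, h2_target < 1)
  structure(list(n = as.integer(n), p = as.integer(p), maf_range = maf_range,
                 ld_rho = ld_rho, n_qtl_add = as.integer(n_qtl_add),
                 n_qtl_epi = as.integer(n_qtl_epi),
                 epi_window = as.integer(epi_window),
                 epi_var_frac = epi_var_frac, h2_target = h2_target,
                 seed = as.integer(seed)),
            class = "simConfig")
}

# One haplotype panel: n x p AR(1) latent Gaussians thresholded at the
# per-marker MAF quantile, so marker k carries the minor allele with
# probability maf[k] and adjacent markers are correlated (local LD).
sim_haplotypes <- function(n, p, maf, rho) {
  x <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && p > 1) {
    s <- sqrt(1 - rho^2)
    for (k in 2:p) x[, k] <- rho * x[, k - 1L] + s * x[, k]
  }
  thr <- qnorm(maf)
  sweep(x, 2, thr, "<") * 1L
}

#' Simulate genotypes with local linkage disequilibrium
#'
#' Draws per-marker MAFs uniformly in `maf_range`, generates two latent
#' haplotype Gaussian processes with AR(1) correlation `ld_rho` along the
#' genome, thresholds each at the MAF quantile and sums the two haplotypes
#' to dosages in 0/1/2. Reproducible given `cfg$seed`.
#'
#' @param cfg a [simConfig()].
#' @return a [GenotypeMatrix-class].
#' @examples
#' Z <- simulateGenotypes(simConfig(n = 50, p = 20))
#' table(dosages(Z))
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  maf <- runif(cfg$p, cfg$maf_range[1], cfg$maf_range[2])
  H1 <- sim_haplotypes(cfg$n, cfg$p, maf, cfg$ld_rho)
  H2 <- sim_haplotypes(cfg$n, cfg$p, maf, cfg$ld_rho)
  GenotypeMatrix(H1 + H2, markerIds = sprintf("m%04d", seq_len(cfg$p)))
}

#' Simulate a trait with additive and local epistatic architecture
#'
#' Genetic values combine additive effects on standardized dosages at
#' `n_qtl_add` loci with pairwise products of standardized dosages at
#' `n_qtl_epi` locus pairs lying within `epi_window` of each other. The two
#' parts are rescaled so epistasis contributes `epi_var_frac` of the
#' genetic variance, and residual noise is added so that
#' `Var(g) / Var(y)` targets `h2_target`
#' (`sigmaE2 = Var(g) (1 - h2) / h2`).
#'
#' @param Z a [GenotypeMatrix-class], typically from [simulateGenotypes()].
#' @param cfg the [simConfig()] (its `seed + 1` seeds the trait draw so the
#'   same genotypes can carry independent trait replicates via the seed).
#' @return list with `y` (phenotypes), `g` (true genetic values), and
#'   `ledger`, a data.frame of all causal loci/pairs and their effects.
#' @export
simulateTrait <- function(Z, cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  Zm <- as_dosage_matrix(Z)
  n <- nrow(Zm); p <- ncol(Zm)
  if (cfg$n_qtl_add == 0L && (cfg$n_qtl_epi == 0L || cfg$epi_var_frac == 0))
    stop("no QTL: the genetic variance would be zero")
  set.seed(cfg$seed + 1L)
  mu_col <- colMeans(Zm)
  sds <- apply(Zm, 2, sd)
  ok <- which(sds > 0)
  if (length(ok) < 2L) stop("fewer than two polymorphic markers")
  std_col <- function(j) (Zm[, j] - mu_col[j]) / sds[j]
  # additive part (loci in original genome coordinates)
  add_loci <- sort(sample(ok, min(cfg$n_qtl_add, length(ok))))
  add_eff <- rnorm(length(add_loci))
  g_add <- numeric(n)
  for (k in seq_along(add_loci))
    g_add <- g_add + add_eff[k] * std_col(add_loci[k])
  # epistatic part: products of standardized dosages at pairs lying within
  # epi_window of each other along the genome
  g_epi <- numeric(n)
  epi_tab <- NULL
  if (cfg$n_qtl_epi > 0L && cfg$epi_var_frac > 0) {
    has_partner <- vapply(ok, function(j) {
      d <- seq_len(cfg$epi_window)
      any((j + d) <= p & (j + d) %in% ok)
    }, logical(1))
    cand <- ok[has_partner]
    if (!length(cand)) stop("no polymorphic pairs within epi_window")
    first <- sample(cand, min(cfg$n_qtl_epi, length(cand)))
    second <- vapply(first, function(j) {
      d <- seq_len(cfg$epi_window)
      opts <- (j + d)[(j + d) <= p & (j + d) %in% ok]
      if (length(opts) == 1L) opts else sample(opts, 1L)
    }, integer(1))
    epi_eff <- rnorm(length(first))
    for (k in seq_along(first))
      g_epi <- g_epi + epi_eff[k] * std_col(first[k]) * std_col(second[k])
    epi_tab <- data.frame(kind = "epistatic", locus = first,
                          partner = second, effect = epi_eff)
  }
  f <- cfg$epi_var_frac
  va <- var(g_add); ve <- var(g_epi)
  w_add <- if (f < 1 && va > 0) sqrt((1 - f) / va) else 0
  w_epi <- if (f > 0 && ve > 0) sqrt(f / ve) else 0
  g <- w_add * g_add + w_epi * g_epi
  vg <- var(g)
  if (vg == 0) stop("genetic variance is zero; check QTL settings")
  sigmaE2 <- vg * (1 - cfg$h2_target) / cfg$h2_target
  y <- g + rnorm(n, 0, sqrt(sigmaE2))
  ledger <- rbind(
    data.frame(kind = "additive", locus = add_loci, partner = NA_integer_,
               effect = add_eff * w_add),
    if (!is.null(epi_tab))
      transform(epi_tab, effect = effect * w_epi))
  list(y = as.numeric(y), g = g, ledger = ledger)
}
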