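---
title: "Methods: the banded neural lasso for genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the banded neural lasso for genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The prediction problem

Genomic selection ranks breeding candidates by genetic values predicted from
genome-wide SNP markers. The standard whole-genome regression model writes a
continuous phenotype $y$ for $n$ lines as

$$ y = X\beta + Zw + \epsilon, $$

with $Z$ the $n \times p$ dosage matrix (allele counts 0/1/2, markers in
genome order), $w$ the marker effects and
$\epsilon \sim N(0, I\sigma_e^2)$. Because $p \gg n$, the fit must be
regularized — the lasso ($\ell_1$), ridge ($\ell_2$) and the elastic-net
compromise are the classical penalized choices, and GBLUP treats the genetic
values as a random effect with covariance proportional to a genomic
relationship matrix. All of these are additive: no interaction between loci
enters the predictor.

## The banded neural model

This package models *local* epistasis — interactions among markers lying in
a short genomic segment — with a single-layer neural architecture whose
linear map is a banded $p \times p$ matrix $C$: only the main diagonal and
the $N$ sub/superdiagonals on each side are nonzero, so each output unit
sees a window of $2N+1$ neighboring loci. Writing $c_{n,\cdot}$ and
$b_{n,\cdot}$ for the weight and bias vectors of diagonal offset $n$, the
prediction for individual $j$ is

$$ \Lambda(z_j) \;=\; \sum_{n=-N}^{N}\sum_{i=1}^{p}
   \varphi_n\!\left(c_{n,i}\, z_{j,i+n} + b_{n,i}\right), $$

with $z_{i}=0$ outside $1..p$ (zero padding) and, at the default $N=2$,
$\varphi_n = \mathrm{ReLU}$ for the inner offsets $n \in \{-1,0,1\}$ and the
identity for $n = \pm 2$. The parameters are found by minimizing

$$ \sum_{j=1}^{n}\left[y_j - \Lambda(z_j)\right]^2
   + \lambda \sum_{n=-N}^{N}\sum_{i=1}^{p}\left(|c_{n,i}| + |b_{n,i}|\right), $$

an $\ell_1$-penalized squared-error objective in lasso style. If every
activation is made linear the model collapses to an overparametrized banded
lasso ([`fitNeuralLasso()`] with `act = rep("identity", 2N+1)`), which is
the natural ablation for asking whether the thresholding nonlinearity earns
its keep; with $N=0$, identity activation and biases disabled it is exactly
the lasso's linear predictor.

Two modeling consequences are worth stating plainly. First, each summand is
a function of a *single* genotype value, so the predictor is a sum of
per-locus piecewise-linear dose-response curves; the band does not form
products of neighboring genotypes. What couples a neighborhood is that the
same locus contributes through $2N+1$ different (weight, bias, activation)
triplets, and under linkage disequilibrium the thresholded terms absorb the
nonlinear components that local interactions project onto each marker's
dosage. Second, because the bias enters *inside* the activation, a ReLU
unit with a learned positive bias reproduces a linear response on the
observed dosage range — the nonlinearity is optional per unit, learned, not
imposed. The boundary convention follows the model equation literally: the
bias terms of out-of-range positions are still added (and passed through
the activation); they contribute an individual-independent constant.

## Training

The objective is minimized by full-batch Adam (the batch is the whole
sample) for 3000 iterations, with a cosine learning-rate decay

$$ \mathrm{lr}(s) = \mathrm{lr}_{\mathrm{end}} +
   \tfrac12(\mathrm{lr}_{\mathrm{start}} - \mathrm{lr}_{\mathrm{end}})
   (1 + \cos(\pi s/T)), $$

from $10^{-3}$ to $10^{-5}$. Update $t$ uses $\mathrm{lr}(t-1)$, so the
first step runs at `lr_start`. Choices the protocol leaves open were fixed
as follows, once:

* **Initialization.** Weights i.i.d. uniform on $(-0.01, 0.01)$, seeded;
  biases at $+0.01$ so every ReLU unit starts in its active region (an
  all-zero start would leave boundary units with zero gradient under the
  convention $\mathrm{ReLU}'(0)=0$).
* **$\ell_1$ handling.** A plain subgradient ($\lambda\,\mathrm{sign}$,
  with $\mathrm{sign}(0)=0$) inside Adam, as a straightforward autodiff
  implementation of the objective would produce. There is no proximal or
  soft-threshold step, so fitted parameters are *approximately*, not
  exactly, sparse — small oscillations around zero of the order of the
  final learning rate remain. A consequence documented in
  `validationScore()`: penalty-dominated fits give nearly but not exactly
  constant predictions, so the degenerate-score rule (score 0) triggers
  only on exact constancy or zero-variance validation phenotypes.
* **Divergence guard.** Training aborts, naming the iteration, if the
  objective becomes non-finite or exceeds $10^{12}$ times its initial
  value.
* **Loss trace.** `lossTrace(fit)[t]` is the objective at the parameters
  *entering* iteration $t$; element 1 is therefore the initial objective.

The forward map, subgradient and Adam loop are compiled (RcppArmadillo), as
is the coordinate-descent elastic net; at these problem sizes a fit at
$n=400$, $p=800$, $N=2$ takes on the order of 20 s on one core.

## Tuning the penalty weight

$\lambda$ is tuned on a *single* train/validation split by a modified
bisection (`tuneLambda()`): evaluate the validation Pearson correlation at
the interval endpoints $a$, $b$ and the midpoint $(a+b)/2$; if an endpoint
is best, shift the interval (same width) so that endpoint becomes the new
midpoint — one new evaluation; if the midpoint is best, halve the interval
around it — two new evaluations. Decisions left open, fixed as follows: on
exact ties the midpoint wins (halving guarantees termination); shifted
intervals are clipped at 0 from below; the search stops after `max_steps`
(default 10) steps or when the interval is narrower than `min_width`; the
default interval is $[10^{-3}, 10^{2}]$ on the raw objective scale, with an
optional $\log_{10}$ mode. The midpoint is read as $(a+b)/2$ — the standard
bisection midpoint. The best $\lambda$ *observed* is always returned, never
an unevaluated point. The tuned $\lambda$ is then held fixed across all CV
repeats, matching the single-realization tuning of the protocol.

## Baselines

* **Elastic net** (`enetFit()`): cyclic coordinate descent with
  soft-thresholding on the objective
  $\sum_i r_i^2 + \lambda\sum_j[\frac{1-\alpha}{2}w_j^2 + \alpha|w_j|]$,
  unpenalized intercept via centering; $\alpha = 0.33$ by default, the
  cross-validated mixing used in the evaluation protocol. Note the penalty
  is on the raw sum-of-squares scale; glmnet's $\lambda$ corresponds to
  ours divided by $2n$ (and glmnet additionally standardizes the response
  internally, so exact agreement requires a unit-variance response).
* **GBLUP** (`gblupFit()`): the genomic relationship matrix uses VanRaden
  method-1 scaling, $K = Z_cZ_c^{\top}/\,2\sum_k p_k(1-p_k)$ — the protocol
  names no formula; this is the convention of standard GBLUP software.
  Variance components are estimated by *restricted* maximum likelihood
  (REML, the convention of the GBLUP literature) in spectral form: the
  mean-projected $K$ is eigendecomposed once and the restricted likelihood
  is maximized over $\log(\sigma_g^2/\sigma_e^2)$ on $[-12, 12]$ with
  `optimize()`; a solution at the boundary raises a warning and clamps
  $\sigma_g^2$ at 0 when negligible. SNP heritability is
  $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)$.
* Bayesian whole-genome regressions (BayesA/B, Bayesian lasso) require
  MCMC machinery and are out of scope; `evaluateMethod()` accepts any
  externally fitted predictor through its function arguments.

## Evaluation

`kfoldSplits()` partitions a seeded permutation into $k$ folds whose sizes
differ by at most one (5 folds, i.e. 80/20, by default); `evaluateMethod()`
fits on each training fold — centering phenotypes by the *training-fold*
mean only, so no information leaks from the validation fold — and records
the Pearson correlation between predicted and observed phenotypes on the
held-out fold. The default scheme repeats the partition 50 times and
averages, and precomputed splits can be shared so that methods compared in
one run see identical partitions.

## The synthetic test bed

`simulateGenotypes()` draws per-marker MAFs uniformly (default
$U(0.1, 0.5)$), generates two latent haplotype Gaussian AR(1) processes
along the genome (adjacent-marker correlation `ld_rho`, default 0.5 — a
realistic level for adjacent markers on a dense panel), thresholds each at
the MAF quantile and sums the haplotypes into 0/1/2 dosages. This gives
local, distance-decaying LD with no external simulator dependency.
`simulateTrait()` adds genetic values with an additive part (normal effects
on standardized dosages) and a local epistatic part (normal effects on
*products* of standardized dosages at pairs within `epi_window` loci,
default 2, so every pair fits inside the model's 5-locus window);
the parts are rescaled so epistasis contributes `epi_var_frac` of the
genetic variance, and residual noise is calibrated to the *realized*
genetic variance so that $\mathrm{Var}(g)/\mathrm{Var}(y)$ hits
`h2_target` up to sampling noise in the residuals. Effects act on
standardized (not raw) dosages so this variance budgeting stays tractable.

What the simulator does *not* emulate: population structure and family
relatedness, allele-frequency spectra shaped by selection, long-range LD,
dominance, genotyping error, and trait non-normality. Tests passing on this
test bed therefore show the estimators and the harness are correct and that
the model behaves as designed under its own assumptions — not that any
particular accuracy will transfer to a real rice or mouse panel.

## Quality control and file formats

`readGenotypes()` accepts delimited dosage tables and PLINK `.raw` additive
files, enforcing the strict 0/1/2/NA coding with the offending cell named
on error. `qcFilter()` drops markers with MAF below 0.05, missingness above
20 %, and exact duplicates (keeping the first), then mean-imputes the
surviving missing entries — imputed dosages are fractional, which the
model accepts. The MAF rule is applied in the conventional direction
(markers *below* the threshold are excluded); QC shorthand sometimes prints
the inequality the other way. Marker adjacency is column order; the package
does not break neighborhoods at chromosome boundaries (the window is small
and at most $2N$ marker pairs per boundary are affected; users with
multi-chromosome panels can fit per chromosome if this matters).

## Problem sizes in the tests and acceptance script

All verification data are generated by the simulator at fixed seeds. The
package's own verification runs use: forward-map equivalence on 100 random
small instances ($n \le 20$, $p \le 50$, $N \le 2$); the lasso reduction at
$n=200$, $p=100$; heritability recovery at $n=500$, $p=1000$ over 10
seeds; additive signal recovery at $n=400$, $p=800$ with 5-fold CV and 2
repeats; and the ReLU-vs-linear ablation at $n=250$, $p=200$ over 10 seeds
with 5-fold CV, one repeat per seed and $\lambda$ tuned once on the first
seed's split. These sizes keep a full verification run on one desktop core
in the tens of minutes while leaving the statistical comparisons
well-powered.

## Known limitations

* The subgradient treatment of the $\ell_1$ term yields approximate
  sparsity only; exact variable selection should use `enetFit()`.
* The banded architecture represents per-locus nonlinear dose response
  within LD neighborhoods, not explicit product interactions; traits whose
  epistasis is invisible in single-locus projections will not benefit. On
  the package's own test bed (pairwise products of standardized dosages,
  adjacent-marker LD ≈ 0.5) the gap between the best additive-nonlinear
  predictor and the best linear predictor of the genetic values is small,
  so the ReLU-vs-linear comparison in the verification suite is a
  demanding, low-powered check at desk-scale sample sizes — its outcome
  should be read together with this structural point.
* Because the L1 penalty also shrinks the biases, heavily penalized fits
  push ReLU units back into their linear regime (on the nonnegative dosage
  support a ReLU with nonnegative bias *is* linear); the learned
  nonlinearity is therefore most visible at moderate penalty weights.
* REML uses a dense eigendecomposition — $O(n^3)$, fine to a few thousand
  individuals, not for biobank scale.
* One trait at a time; fixed effects should be pre-corrected before
  modeling (only the overall mean is handled internally).
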