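---
title: "Latent correlations, reliability corrections, and path models for longitudinal attainment data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent correlations, reliability corrections, and path models for longitudinal attainment data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentpath)
```

## The problem

Longitudinal studies of educational attainment — secondary-school grades,
medical-school examinations, post-graduate memberships — rarely yield clean
continuous measurements. Grade schemes have ceilings: when the best three
A-levels are scored A = 10 ... E = 2 with a maximum of 30 points, a majority
of a strong cohort can sit exactly at 30, and the information that would
separate them is simply not recorded. Other outcomes are coarsely grouped
(distinction / satisfactory / resit / fail) or binary (on a specialist
register or not). Each of these distortions attenuates the observed Pearson
correlation relative to the correlation of the underlying traits, and
selected cohorts add restriction of range on top. `latentpath` provides the
machinery to estimate the *latent* correlations, to correct composite
reliabilities, and to assemble the corrected correlations into causal-path
summaries, together with a synthetic cohort generator that reproduces all of
these distortions with known truth.

## The latent correlation model

For a pair of measures we assume a latent bivariate normal
$(X^*, Y^*)$ with means $\mu_x, \mu_y$, SDs $\sigma_x, \sigma_y$, and
correlation $\rho$. Each observation is mapped to either a point or an
interval on the latent scale (`to_interval()`):

* a continuous value below any ceiling is the point itself;
* a value recorded at a ceiling $c$ is the interval $[c, \infty)$ (and
  symmetrically for floors);
* ordinal category $k$ of a margin with thresholds
  $\tau_1 < \dots < \tau_{K-1}$ is the cell $(\tau_{k-1}, \tau_k]$;
* a binary outcome is one of the two half-lines around its single
  threshold.

The likelihood of a pair is then the bivariate normal density (two points),
a marginal density times a conditional interval probability (point and
interval), or a rectangle probability (two intervals). This single interval
likelihood specializes to the censored-normal, biserial/polyserial,
tetrachoric, and polychoric correlations depending only on the two
measurement kinds declared in `var_spec()`, which is how the pipeline
dispatches pair types without separate estimators. Categorical margins are
identified by fixing $\mu = 0$, $\sigma = 1$.

Rectangle probabilities use the Drezner–Wesolowsky Gauss–Legendre quadrature
with the Genz reformulation beyond $|\rho| = 0.925$; in tests the routine
agrees with an independent adaptive-quadrature oracle to better than 1e-9
and partitions of the plane sum to one within 1e-8. Cells of
interval–interval pairs are aggregated by unique pattern, so a tetrachoric
likelihood evaluation costs four rectangle calls regardless of n.

## Sampling and chain conventions

The posterior is explored by a random-walk Metropolis sampler in the
unconstrained parameterization
$(\mu, \log\sigma, \tau_1, \log\Delta\tau, \operatorname{atanh}\rho)$
with flat priors on that scale — keeping $\sigma$ positive, thresholds
ordered, and $\rho$ inside $(-1, 1)$ while mimicking maximum-likelihood-like
use of the chain. Two features follow the DRAM family of samplers:

* **Adaptation.** After a non-adaptive opening phase (first 10% of the
  chain) the proposal covariance is re-estimated from the full chain
  history, scaled by $2.38^2/d$ with a small diagonal jitter.
* **Delayed rejection.** A rejected move is retried once from a proposal
  shrunk by a factor of 5, accepted with the two-stage probability that
  preserves the stationary distribution.

Chains default to 5,000 iterations. Estimates and standard errors are the
mean and SD of the final 2,000 draws, and 95% intervals are the 2.5th and
97.5th percentiles of those draws; burn-in is therefore implicit in the
window. `stability_check()` operationalizes the usual visual trace
inspection as a Geweke-style z statistic comparing the first and last
quarters of the estimate window, with batch-means variances so that
autocorrelation widens the standard error rather than inflating false
alarms; |z| > 3 flags instability, and a constant chain is stable by
convention.

Thresholds of categorical margins are sampled jointly with $\rho$ by
default (one-step). A two-step mode (`fixed_thresholds = TRUE`) pins them
at the marginal inverse-normal quantiles, which is the classical two-stage
polychoric recipe; the two agree closely on well-behaved data and the
two-step mode is useful as a cross-check. Initialization uses the naive
Pearson correlation (on category codes where needed), moments of the
non-censored values, and marginal quantiles. Pairs are formed by pairwise
deletion and each estimate reports its pair count, matching the convention
of reporting per-pair n in correlation tables.

## Reliability and power utilities

The classical test-theory operations are closed-form:
Cronbach's $\alpha = \frac{k}{k-1}(1 - \sum_i s_i^2 / s_T^2)$;
the Spearman–Brown prophecy $R = kr/(1+(k-1)r)$ and its exact inverse
$r = R/(k-(k-1)R)$, used to back-calculate single-component reliabilities
from composite ones; disattenuation $r_{xy}/\sqrt{r_{xx} r_{yy}}$, reported
unclipped (with a warning) when it exceeds 1, since clipping would hide
exactly the sampling-error signal the value carries; a two-part composite
reliability computed as Spearman–Brown at $k = 2$ on the mean of the two
component reliabilities, the only two-number formula consistent with
quoting a single "overall" value; and normal-approximation power for a
two-sample mean comparison with noncentrality $d\sqrt{n_1 n_2/(n_1+n_2)}$.
The power routine takes the number of tails explicitly because directional
and non-directional versions differ visibly at moderate power.

## Path models

`fit_backbone()` regresses each variable in causal order on all causally
prior variables, eliminating the least significant predictor (largest
p-value at or above the threshold, default 0.05) one at a time until every
survivor is significant. Removed predictors never re-enter; ties are broken
by removing the causally later predictor, a deterministic and logged rule.
Coefficients are standardized betas, so edge weights are comparable across
pairs and can drive the width of arrows in the exported DOT diagrams.
Complete-case deletion is used per target regression — pairwise deletion is
incoherent for multiple regression. Ordinal outcomes enter as their numeric
scores. The resulting graph is acyclic by construction, and under an
all-null simulation the per-candidate retention rate stays at the nominal
level.

## The synthetic cohort generator

The generator exists to validate the estimators under known truth, and its
defaults encode the observable structure of the cohorts the methods were
designed for:

* **Simplex correlations.** Latent stage scores are multivariate normal
  with `corr(i, j)` equal to the product of intervening lag-1
  correlations, the statistical signature of stage-wise causal chains.
  Preset lag-1 values sit in 0.5–0.7, the range typical of adjacent
  attainment measures.
* **Selection.** Entrants are the top fraction on an early stage
  (deterministic truncation by default — the cleanest restriction-of-range
  testbed; logistic selection is available for realism). The truncated
  group shows the reduced SD and attenuated correlations that motivate
  construct-level corrections.
* **Observation.** Each stage may be recorded exactly, at a grade ceiling
  placed at a quantile (the flagship preset puts 62.5% of entrants at the
  A-level maximum), as ordinal categories cut at cumulative-proportion
  quantiles (the 1985-style preset uses 6.7/28.3/53.3/11.7% from fail to
  distinction), or as a binary indicator. Measurement noise is
  parameterized by a reliability (default 0.8 in the presets, consistent
  with single-year examination reliabilities around 0.6–0.9) and keeps
  unit variance.
* **Uptake.** Post-graduate examinations are attempted with probability
  `plogis(a + b * prior latent score)`; the preset slope of 1.5 encodes
  clearly performance-dependent uptake, and the intercept is calibrated on
  the realized entrant scores so the attempt fraction hits the configured
  target (34.6% in the flagship preset) in expectation. Slopes are
  calibration choices of the generator: the studies report uptake
  fractions and attempter/non-attempter differences, not logistic
  coefficients.

All randomness flows from the single config seed; identical configs give
identical tables, and `run_end_to_end()` bundles are byte-identical across
repeated runs. The truth record (population correlation matrix, selection
rule, censoring points, thresholds, uptake coefficients, seed) is retained
for recovery tests.

What the generator does *not* emulate: non-normal latent traits, grade
inflation over calendar time, demographic structure beyond a binary
covariate mean shift, and missingness mechanisms other than selective
uptake. Passing recovery tests therefore demonstrates correctness of the
estimators under the assumed latent-normal model, not robustness to
violations of it.

## Numerical choices and problem sizes

* Rectangle probabilities: 6/12/20-point Gauss–Legendre by $|\rho|$ band;
  accuracy well beyond the 1e-8 the likelihood needs.
* $\rho$ is bounded away from $\pm 1$ only through the
  $\operatorname{atanh}$ parameterization; degenerate parameter values
  yield a log-likelihood of $-\infty$ (a rejected move), never an
  exception.
* Validation suites run at sizes where Monte-Carlo error is small relative
  to the tolerances checked: n = 2000 for the tetrachoric/grid-search
  comparison (tolerance 0.03), n = 5000 for the no-censoring limit
  (tolerance 0.03), and 100 replicates of n = 1000 per true correlation
  for CI coverage under a 60% ceiling (coverage bound 85%, loose enough to
  absorb replicate noise).
* The minimum pairwise n for reporting a corrected correlation is 10,
  configurable; published tables report pairs down to n ≈ 45, and below a
  few dozen pairs the latent model is weakly identified anyway.

## Known limitations

Only pairwise (bivariate) latent correlations are estimated; a full joint
latent-normal model over more than two variables is out of scope, as are
EM-based polyserial estimation and construct-validity corrections for
restriction of range (which require applicant-pool information beyond the
entrant data). The path model is ordinary least squares on observed scores
— it does not propagate the uncertainty of the censoring corrections into
the path coefficients, and latent-variable structural equation modelling is
deliberately not attempted. The functions, `run_end_to_end()`, and this
vignette are the package's interface; there is no separate command-line
binary.
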