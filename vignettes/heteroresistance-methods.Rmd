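---
title: "Estimating heteroresistance from the inoculum effect: models, estimators and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heteroresistance from the inoculum effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heterores)
```

## The model and its assumptions

`heterores` rests on one parametric assumption: within a clonal
population, single-cell resistances to the stressor are lognormally
distributed.  Writing $x$ for a cell's resistance in mM,

$$\log_{10} x \sim N(\mu, \sigma^2),$$

so the population median $10^\mu$ is the IC50 (the concentration
inhibiting half the cells) and $\sigma$ — the SD of
$\log_{10}(\text{resistance})$, dimensionless on that scale — is the
*heteroresistance*.  Sigmoidal dose-response curves on log concentration
(Hill-type fits) imply exactly this family, and in the yeast data that
motivated the package the lognormal fits percent-survival curves slightly
better than a plain normal on raw mM.  A plain-normal mode
(`scale = "linear"` in `fit_inoculum_effect()`) is retained for
comparison, but all derived quantities default to the lognormal form.
The degenerate case $\sigma = 0$ is deliberately legal: it expresses a
perfectly homogeneous population, for which the survival curve becomes a
step function and the inoculum effect vanishes.

Three consequences of the model drive everything else:

1. **Inoculum effect.** An inoculum of $n$ cells grows at concentration
   $c$ iff its most resistant cell exceeds $c$.  The expected maximum of
   $n$ normal draws is approximately
   $\mu + \sigma\, z(n)$ with
   $z(n) = \Phi^{-1}\!\big((n - \pi/8)/(n - \pi/4 + 1)\big)$
   (`expected_max_quantile()`), an order-statistic approximation accurate
   to well under 1% against Monte-Carlo maxima for $n$ from 10 to
   $10^4$ (the test suite checks this).  MIC readings at several inoculum
   sizes therefore trace a straight line in $z(n)$ whose intercept and
   slope are $\mu$ and $\sigma$.
2. **Model MIC.** The 99.99th percentile of single-cell resistance,
   $10^{\mu + \sigma \Phi^{-1}(0.9999)}$ (`mic_model()`), summarises
   "the MIC of 10,000 cells" without reference to a particular assay.
   Note $\Phi^{-1}(0.9999) \approx 3.719$ is *not* the same as
   $z(10^4) \approx 3.843$: the former is a population percentile, the
   latter an expected maximum; the package keeps them distinct and the
   predicted 10^4-cell MIC always dominates the model MIC.
3. **Dose-response curve.** The surviving fraction at concentration $c$
   is $1 - \Phi\big((\log_{10} c - \mu)/\sigma\big)$
   (`survival_fraction()`), fitted directly to plate-count
   percent-survival data as an independent estimation route.

The log base is base 10 throughout.  This choice is forced by internal
consistency of the bundled panel: for every strain,
$10^{\log_{10}(\mathrm{IC50}) + 3.719\,\sigma}$ reproduces the tabulated
model MIC to within 2.9% (natural logs would be off by ~20%).  The
"heteroresistance (SD, mM)" labelling convention for $\sigma$ is treated
as shorthand; the quantity is dimensionless on the log10(mM) scale.

## Estimators

**Inoculum-effect fit.** Given observations $(n_i, \mathrm{MIC}_i)$, the
estimator minimises
$\sum_i \big(\log_{10}\mathrm{MIC}_i - \mu - \sigma z(n_i)\big)^2$
subject to $\sigma \ge 0$.  Because the model is linear in
$(\mu, \sigma)$ once $z(n)$ is computed, this is solved *exactly* by
constrained ordinary least squares rather than by an iterative
non-linear optimiser: the optimum is identical, there are no starting
values or convergence failures, and the boundary case is explicit — a
negative unconstrained slope (noisy, flat data) is clamped to
$\sigma = 0$ and flagged (`sigma_clamped`), since flat data legitimately
estimate "no heteroresistance".  A brute-force grid search over
$(\mu, \sigma)$ is kept in the test suite as an independent optimality
oracle.  Residuals are taken on $\log_{10}$ MIC, consistent with the
lognormal model; the `linear` scale mirrors the plain-normal variant.

**Dose-response fit.** Percent survival is fitted to
$100\,(1 - \Phi((\log_{10} c - \mu)/\sigma))$ by bounded
quasi-Newton least squares (`nlminb`, $\sigma \ge 0$), started at
$\mu_0 = \log_{10}$ of the concentration whose observed survival is
nearest 50% and $\sigma_0 = 0.05$, with up to five jittered restarts.
Zero-concentration rows are the normalisation controls and are excluded
from the residuals — they define the 100% reference, not the curve.
Data entirely above or entirely below 50% survival cannot locate $\mu$
and are rejected as under-determined rather than extrapolated.  On
noise-free model data the fit is a projection (parameter error
below $10^{-6}$), which the tests assert.

**Replicate structure.** One curve is fitted per biological replicate;
`aggregate_fits()` then reports the mean and SEM of IC50,
heteroresistance and model MIC across replicates.  The model MIC is
averaged over per-replicate values — not recomputed from the mean
$\mu$ and mean $\sigma$ — because the percentile transform is
non-linear; the bundled panel's tabulated values were produced the same
way, which is why they agree with $10^{\mu + 3.719\sigma}$ only to a few
percent, not exactly.

**Bootstrap.** `bootstrap_fit()` resamples observation *rows* with
replacement (case resampling, appropriate for heteroscedastic
count-derived data; residual resampling would assume exchangeable
errors), refits each resample, and reports 2.5/97.5 percentile intervals
plus a pointwise 95% envelope of predicted curves.  Resamples that lose
identifiability are dropped and counted; more than 20% failures aborts
with a "bootstrap unstable" error rather than returning a quietly
unreliable interval.  Runs are byte-reproducible given the seed, and the
caller's RNG stream is restored afterwards.

## What the simulator emulates — and what it does not

`simulate_mic_exp()` reproduces the microdilution assay mechanics:

* an arithmetic concentration grid (default 0 to 20 mM in 0.125 mM
  steps — matching a 20 mM stock and typical increments);
* nominal inocula of $10^2$–$10^5$ cells/well, with the *actual* cell
  number Poisson-distributed around nominal (plate-count calibration of
  real inocula implies exactly this noise); switchable off for exact
  tests;
* binary growth per well: a well grows iff at least one cell's
  resistance strictly exceeds the concentration.  This is drawn from the
  closed form $P(\text{no growth}) = \Phi((\log_{10} c - \mu)/\sigma)^n$
  rather than by sampling $n$ cells, which is mathematically identical
  and makes $10^5$-cell wells O(1);
* MIC scoring.  `any_clear` (default) scores the lowest concentration at
  which at least one of the technical-replicate wells fails to grow —
  the literal protocol rule in the motivating assay; `all_clear` is the
  conventional rule (no technical replicate grows).  The full grid is
  simulated without early stopping so both rules can be scored from the
  same draws; `any_clear` $\le$ `all_clear` holds path-wise.  MICs beyond
  the grid are flagged censored and excluded from fits with a warning,
  not imputed.

`simulate_dose_response()` emulates the agar plating route: colony
counts are $\mathrm{Binomial}(\text{cells plated},\ \text{survival
fraction})$, normalised to each replicate's zero-concentration control
plate; the two default inocula ($10^4$ and $10^2$ cells) give counting
resolution in complementary survival ranges.

Deliberately *not* modelled: growth kinetics and time-to-detection (a
well is growth/no-growth at endpoint; slow-growing resistant cells that
would appear after weeks are counted as growth), cell-density effects on
the MIC (stressor depletion, quorum-like phenomena) as distinct from
cell-number effects, stressor metabolism, correlation between technical
replicates sharing a medium batch, and agar-versus-broth differences.
Passing recovery tests therefore show that the *estimators* are correct
under the stated stochastic model, not that real assays are free of
those confounds — with real data, a dose-response comparison is the
appropriate control when cell-density effects are plausible.

## Study conditions and numerical choices

The simulation studies shipped in the tests and the acceptance script
use one fixed set of conditions, chosen once to mirror a realistic assay
and not revisited: $\mu = \log_{10}(4.0)$, $\sigma = 0.07$ (mid-range
values for the bundled panel), the default design above, 100 runs for
recovery means, 200 runs at $B = 500$ for bootstrap coverage, $10^4$
wells per cell of the well-probability grid, and $10^5$ replicates for
the order-statistic Monte-Carlo oracle.  These sizes give Monte-Carlo
error comfortably below the quantities being measured while keeping the
whole suite in tens of seconds on one CPU.  The Monte-Carlo oracle for
$E[\max \text{ of } n \text{ normals}]$ draws maxima directly via the
exact inverse-CDF representation $\Phi^{-1}(U^{1/n})$, which is the same
distribution as the maximum of $n$ draws at a fraction of the cost.

Two known biases of the *assay* (not the estimator) are worth stating
plainly, since the package measures rather than hides them.  Under
`all_clear` scoring with $k$ technical replicates, requiring all $k$
wells clear makes the scored MIC behave like the expected maximum of
roughly $k \cdot n$ cells, inflating the fitted IC50 (about +7% at the
default $k = 4$) and slightly shrinking $\sigma$ (about -5%); the
mirror-image rule `any_clear` biases in the opposite direction.  A
case-resampling bootstrap cannot see this scoring-rule bias, so nominal
95% intervals for $\sigma$ under the default design cover the truth in
roughly 80–85% of runs, not 95%.  Inference from a single assay design
should treat the scoring rule as part of the measurement model; fitting
with an effective inoculum of $k \cdot n$ would remove most of the bias
but is not done by default, to keep the estimator faithful to how such
data are conventionally analysed.

Other numerical conventions: ties at a grid concentration resolve by the
strict-inequality growth condition (a cell exactly at $c$ does not
grow); the degenerate $\sigma = 0$ survival curve evaluates to 0.5 at
exactly the IC50 (the CDF limit); correlations in `panel_report()` are
computed on untransformed per-strain means (the plotted quantities),
with dispersion comparisons of IC50 on $\log_{10}$ values and of
heteroresistance on raw values; p-values use the exact t-distribution
throughout and no multiple-testing correction is applied.  The
one-tailed p-value reported alongside every correlation is
$p_{\text{two}}/2$ in the direction of the observed association.

## Limitations

The lognormal family is an approximation; genuinely bimodal resistance
(distinct persister subpopulations) would violate it and bias $\sigma$
upward.  Two-inoculum designs identify the model exactly but leave no
residual degrees of freedom for lack-of-fit diagnostics; four or more
inoculum sizes are preferable.  The inoculum-effect route is a
high-throughput *relative* measure of heteroresistance — across methods
its estimates correlate well with dose-response estimates, but
individual fitted distributions are not always superimposable, so
absolute single-strain conclusions should be confirmed by the
dose-response assay.
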