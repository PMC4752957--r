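---
title: "Methods: variance components from full factorial mating designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance components from full factorial mating designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A full factorial (North Carolina II) mating design crosses $n_D$ dams with
$n_S$ sires in all pairwise combinations. For offspring $k$ of dam $i$ and
sire $j$, the latent-scale model is

$$\eta_{ijk} = \mathbf{x}_{ijk}^\top\beta + d_i + s_j + (ds)_{ij}
  \;(+ \text{extra random intercepts}),$$

with independent $d_i \sim N(0, \sigma^2_D)$, $s_j \sim N(0, \sigma^2_S)$,
$(ds)_{ij} \sim N(0, \sigma^2_{D\times S})$. Gaussian responses add
$N(0, \sigma^2_R)$ residuals and are fitted by REML (default) or ML;
binomial and Poisson responses are connected through a link (logit/probit,
log/sqrt) and fitted by the Laplace approximation to the marginal
likelihood (ML only — there is no restricted likelihood for GLMMs).
Fitting is delegated to `lme4` (`lmer`/`glmer`), the de facto standard for
crossed random intercepts; this package owns everything around the fit:
data conversion, the decomposition, the significance, resampling,
interval, and power machinery.

Under the usual quantitative-genetic interpretation (epistasis negligible,
paternal half-sib covariance $=\tfrac14 V_A$), the derived components are

$$V_A = 4\,\sigma^2_S,\qquad V_N = 4\,\sigma^2_{D\times S},\qquad
  V_M = \sigma^2_D - \sigma^2_S .$$

$V_M$ may legitimately be negative and is never clipped. The phenotypic
total is the sum of **all** modeled components: dam, sire, dam-by-sire,
any extra random intercepts, the fixed-effect group variance, the
observation-level (overdispersion) variance when present, and the
residual. Every percentage uses this one total as its denominator — also
the derived ones, which re-use $\sigma^2_S$ and $\sigma^2_{D\times S}$, so
derived percentages plus the residual can exceed 100%.

### Latent-scale residual variance

Nonnormal models have no estimated residual; the link-scale residual is
assigned its distribution-specific variance: $\pi^2/3$ (binomial, logit),
$1$ (binomial, probit), $0.25$ (Poisson, sqrt), and
$\ln(1/e^{\beta_0} + 1)$ (Poisson, log), where $\beta_0$ is the intercept
of a refit containing only the random effects. Percentage decompositions
of different links are therefore comparable only after noting their
different residual constants.

### Fixed effects as a variance component

The variance explained by the fixed effects is extracted as a single
group: the variance of the linear-predictor contributions
$X\hat\beta$, with the $n-1$ denominator (the reference method leaves the
denominator unstated; $n-1$ is used and documented). When binary rows are
collapsed to binomial counts (below), the variance is frequency-weighted
by the per-row trial counts, which is exactly the individual-level value.
The intercept shifts $X\hat\beta$ by a constant and cannot contribute.

### Overdispersion

Proportion (success/failure count) and count responses may be
overdispersed; `quasibinomial`/`quasipoisson` specs add an
observation-level random intercept (OLRE) whose variance absorbs the
excess, and `overdispersion_test()` compares the models with and without
the OLRE by a df-1 ML likelihood-ratio test. Binary rows cannot be
overdispersed and are rejected. The OLRE variance, when present, is a
modeled variance source and is included in the total (the reference
description is silent on this; including it keeps percentages summing
to 100). The df-1 reference at the boundary is conservative, as for every
random-effect LRT here; no mixture correction is applied.

## Numerical choices

- **Optimizer.** `bobyqa` for both `lmer` and `glmer`. On balanced
  factorials the default nloptwrap run stops $\sim 2\times10^{-3}$ away
  from the REML optimum, which is visible against the closed-form
  expected-mean-squares (EMS) solution; bobyqa agrees with it to
  $\sim10^{-7}$ and is faster. Singular (boundary) fits are accepted and
  reported as zero variances.
- **Collapsing binary rows.** For binomial models without an OLRE,
  Bernoulli rows sharing every model variable are aggregated to
  (successes, failures) counts. The likelihood differs only by the
  binomial-coefficient constant $\sum\log\binom{n_g}{k_g}$, which is
  subtracted so reported log-likelihoods stay on the individual scale and
  cancel in every LRT; estimates are identical (asserted in the tests) and
  large designs fit orders of magnitude faster. `n` for BIC is the number
  of individuals.
- **EMS fast engine.** `fit_ems()` implements the classical balanced
  two-way ANOVA moment estimator (truncated at zero), equal to REML at
  interior solutions on balanced data. `fit_resampled(engine = "ems")`
  uses a vectorized version for large bootstrap loops — valid because
  stratified resampling preserves balance. At boundary (truncated)
  solutions EMS and REML genuinely differ; the jackknife always uses
  lme4 because row deletion unbalances the design.
- **Quantiles.** All interval and boxplot quantiles use linear
  interpolation (Hyndman–Fan definition 7), the default of R's generic
  quantile function.
- **Jackknife df.** Delete-$d$ pseudo-values use $M = N/d$ and the
  $t$-interval uses $M$ degrees of freedom, taken literally (not $M-1$).
  The delete-$d$ blocks come from one seeded shuffle followed by
  $\lfloor N/d\rfloor$ sequential deletions.
- **Ties in group comparison.** `compare_groups()` counts strict
  inequalities only; ties are reported and contribute to neither side, so
  comparing a matrix against itself returns $p = 0$ with a tie-count
  warning.
- **Bootstrap p-values.** `pb_fixed()` uses the $(1 + k)/(1 + n_{sim})$
  estimator, never exactly zero.
- **Seeds.** Every stochastic function takes one seed and spawns
  per-iteration sub-seeds; runs are bit-reproducible and the caller's RNG
  stream is left untouched.
- **Failed refits** inside bootstrap/jackknife/power loops are dropped and
  logged (error if more than 10% fail), not propagated.

## Open design points resolved here

- **LRT scale for Gaussian models.** Both REML and ML comparisons are
  exposed (`lrt_random(scale=)`); the spec of the comparison follows the
  fitted method by default. No numerical equivalence with any other
  implementation is claimed.
- **AIC/BIC parameter count** includes all fixed coefficients and all
  variance parameters, residual included.
- **Percentage denominator.** One total for raw and derived percentages
  (see above).
- **Row order of expanded data.** Input row order, with all "1" (or
  first-mapped) records before the next category within a row —
  deterministic; no compatibility with any other tool's ordering is
  claimed.

## The synthetic world

`simulate_factorial()` draws dam, sire and interaction effects from
zero-mean normals with the stated variances, applies the inverse link, and
samples the response. Defaults mirror the reference configurations used
throughout the tests: a gaussian world $(\sigma^2_D, \sigma^2_S,
\sigma^2_{D\times S}, \sigma^2_R) = (0.4, 0.1, 0.1, 1.0)$ at 11×11×40,
and a binomial-logit world $(0.6224, 0.1609, 0.1609)$ at 11×11×300 — the
components implied by a published 14.7/3.8/3.8% decomposition with the
logit residual fixed at $\pi^2/3$. The latent intercept defaults to 0
(success probability 0.5, unit Poisson rate): the reference analyses do
not state theirs, and 0.5 is the least-informative and most
power-favorable operating point for binary survival. Offspring split
evenly across replicates when replicates are declared.

What the generator does **not** emulate: unbalanced family sizes, missing
cells, non-normal parental effect distributions, shared-environment
(tank/tray) confounding unless declared as extras, and
genotype-by-environment interaction. A green parameter-recovery or power
test therefore establishes correctness of the machinery under the stated
world, not robustness to those features.

## Known limitations

- **ML/Laplace bias of the dam component.** With $n_D = 11$ dams, the ML
  estimate of $\sigma^2_D$ is biased downward by roughly
  $\sigma^2_D/n_D$ (there is no REML for GLMMs), plus a smaller Laplace
  term: at the 11×11×300 binomial reference world the mean dam estimate is
  ≈ 0.54 against a truth of 0.6224, a deterministic ≈ 13% shortfall that
  exceeds Monte-Carlo error at a few hundred replicates. Sire and
  interaction components are essentially unbiased. This is a property of
  the estimation method itself; the corresponding acceptance block is
  deliberately left failing.
- **Bootstrap undercoverage for group-level components.** Resampling
  observations within family (or family×replicate) strata reproduces each
  stratum's size but holds the realized dam, sire and interaction effects
  fixed; the resulting component distributions reflect only
  observation-level noise. For $\sigma^2_D$ with 8 dams the bootstrap SD
  understates the true sampling SD ≈ 4.6-fold, and measured 95% interval
  coverage is ≈ 0.22. The intervals are honest descriptions of
  within-design resampling uncertainty — and remain valid for the paired
  group comparison, which differences iterations of the same scheme — but
  they are not frequentist CIs for the population variance. The
  corresponding acceptance block is deliberately left failing.
- **Bootstrap refit means** shift by $O(1/r)$ ($E[\text{boot }MS_E] =
  \frac{r-1}{r} MS_E$): residual down ≈ 10% at $r = 10$, absorbed by the
  interaction.
- **Boundary LRTs are conservative**: the null variance sits on the
  parameter-space boundary, so the χ²₁ reference over-states p-values
  (type-I ≤ α, verified by simulation).
- Delete-one jackknife cost scales with $N$ model refits; use delete-$d$
  for large designs.

## A minimal session

```{r, eval = FALSE}
library(factorialvc)
des <- factorial_design(11, 11, 40,
                        c(dam = 0.6224, sire = 0.1609, dam_sire = 0.1609),
                        family = "binomial", link = "logit")
dat  <- simulate_factorial(des, seed = 2026)
spec <- model_spec("response", family = "binomial", link = "logit")
analyze_factorial(dat, spec)

rs <- resample_by_family(dat, 1000, seed = 1)
cm <- fit_resampled(rs, spec)
ci_bootstrap_t(cm, level = 95)
box_plot(cm, scale = "percent", path = "components.png")
```
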