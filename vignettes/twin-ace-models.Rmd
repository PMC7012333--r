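---
title: "Bivariate liability-threshold ACE sex-limitation models with twinace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate liability-threshold ACE sex-limitation models with twinace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinace)
```

## The model

twinace fits the classical twin design to a pair of traits measured on the
same individuals: a dichotomous trait modeled on the liability-threshold
scale (the motivating application is self-reported type 2 diabetes, with
roughly 8% prevalence) and a continuous trait (log-transformed, age- and
sex-regressed depression-questionnaire residuals). Each trait's variance is
decomposed into additive genetic (A), common environmental (C) and unique
environmental (E) components, and the cross-trait covariance into the
corresponding component correlations rA, rC, rE.

The parameterization is the bivariate Cholesky decomposition: per sex,
lower-triangular 2x2 path matrices `a`, `c`, `e`, so that the A covariance
matrix is `a a'` and so on. This guarantees positive semi-definite component
covariances. The dichotomous trait is the indicator of a standard-normal
latent liability exceeding a threshold; the liability scale is identified by
constraining `a11^2 + c11^2 + e11^2 = 1` per sex. Age is allowed to shift
the threshold linearly (`t_sex + beta_age * (age - 43)`, with the reference
age fixed at 43 years, close to the motivating cohort's mean age), which
absorbs the strong age gradient of type 2 diabetes risk. Because twin-pair
members share their age, an unmodeled age effect would masquerade as shared
environment; modeling it on the threshold keeps the C estimate clean.

Model assumptions are the classical ones: MZ pairs share all, DZ pairs on
average half of the additive genetic effects; equal environments across
zygosity; random mating; and multivariate normal latent liabilities.
Missing phenotypes are marginalized under a missing-at-random assumption
(full-information maximum likelihood); no record is dropped for partial
missingness.

### The sex-limitation ladder

Four nested variants are fitted:

* **HetACEg** — all paths sex-specific; in opposite-sex pairs the 2x2
  cross-sex genetic factor-correlation matrix G is free (4 parameters),
  while the common-environment analogue H stays fixed at the identity.
* **HetACEc** — as above with H free (4 parameters) and G fixed at 0.5 I.
* **HetACE** — quantitative sex differences only: sex-specific paths,
  G = 0.5 I, H = I (the standard DZ structure).
* **HomoACE** — all nine path parameters equated across sexes. Thresholds
  and continuous-trait means remain sex-specific in every variant, and the
  age slope is shared (a parsimony default; it can be freed in the layout).

Comparisons use likelihood-ratio chi-square tests on differences in -2LL
and the AIC under the observed-statistics convention
`AIC = -2LL - 2 df`, `df = (non-missing data values) - (free parameters)`.
Free parameters are counted with the three trait-1 paths per sex as three
estimated parameters and the unit-variance constraint counted separately
(internally the optimizer uses a two-angle spherical reparameterization of
that triple). Under this convention freeing G or H releases exactly 4
parameters and equating the sexes removes exactly 9, matching the published
ladder's test df. A constraint is accepted when its test is non-significant
at 0.05 or when the AIC favors the more parsimonious model by at least 10.

### The likelihood

A family contributes the marginal likelihood of its observed elements.
Continuous elements enter through a multivariate-normal density; binary
elements enter through the conditional normal probability of the liability
rectangle — `(threshold, Inf)` for affected, `(-Inf, threshold]` for
unaffected — given the observed continuous elements. Conditioning on the
continuous elements is analytic, so at most a bivariate rectangle is ever
required. Rectangle probabilities use a vectorized implementation of Genz's
Gauss-Legendre algorithm for the bivariate normal CDF (absolute error below
1e-8 everywhere, near machine precision for moderate correlations; the test
suite checks it against adaptive quadrature). Probabilities below 1e-300
are floored in log space with a warning.

### Numerical choices

* Optimizer: bound-constrained L-BFGS-B over the reparameterized vector;
  convergence factor 1e6 (about 1e-6 absolute on a -2LL of the magnitudes
  seen here), finite-difference step 1e-5.
* Starting values: thresholds at the inverse-normal of observed prevalence,
  component scales at equal thirds of the observed variances, component
  correlations at 0, G and H at their null values. Five starts by default
  (one data-driven, the rest jittered); `fit_ladder()` additionally warm-
  starts each richer or more constrained variant from the HetACE solution,
  which enforces the nesting inequalities up to optimizer slack.
* Degenerate proposals (non-PSD implied covariances, zero conditional
  variances) are rejected by returning a large objective value.
* Profile-likelihood intervals: the bound is where the profile -2LL rises
  by the chi-square(1) quantile, bracketed by a curvature-scaled outward
  search and polished with `uniroot`; intervals are censored at box bounds
  and flagged one-sided. Supported parameters are the free coordinates and
  monotone one-coordinate transforms (rA/rC/rE, the trait-1 heritability
  through its angle, thresholds, means, the age slope). Confidence
  intervals for general functions of several coordinates (such as the
  continuous trait's heritability) would require constrained
  re-optimization machinery and are not provided.

## The synthetic cohort generator

`sim_params()` defaults encode the motivating study's conditions: 842 MZ
pairs, 578 same-sex DZ pairs, 543 opposite-sex pairs, 2019 singletons (the
MZ/DZ sex split is not published and defaults to half/half); age
truncated-normal with mean 43, SD 14.3 on [18, 90], shared within a pair;
threshold at `qnorm(1 - 471/5975)` (the published case count) with an age
slope of 0.02 liability-SD per year — the slope is not published; 0.02 over
a 28-year age SD-range is a realistic gradient for adult-onset diabetes.
Per-sex paths default to the published best-fit standardized components
(female T2DM 77/8/15, female depression 23/13/64, rA = 0.53; male 82/12/6,
7/22/71, rA = 0.38). rC and rE are not published; the generator fixes
rC = 0 and solves rE from the bridge identity so that the implied
phenotypic correlations equal the published 0.15 (female) and 0.06 (male),
giving rE = -0.236 (F) and -0.150 (M).

The continuous trait is normal on the log scale and emitted as
`exp(x) - 1`, by default as the raw continuous value — the preprocessing
log(x+1) then recovers the latent scale exactly — or rounded and clipped to
the integer 0-63 questionnaire range with `bdi = "integer"`. The integer
option floor-censors a substantial mass at 0, a real feature of depression
questionnaires that the Gaussian-liability model does not address; it is
exercised in the preparation tests (the kurtosis-reduction check) but not
used for parameter-recovery checks, which target the fitting machinery
rather than robustness to censoring.

What the generator does *not* emulate: biomarkers conditional on disease
duration or treatment, assortative mating, gene-environment interaction,
age-varying heritability, and twin-specific environments beyond the
A/C/E structure. Passing recovery tests therefore demonstrates that the
estimator inverts its own model correctly at realistic sample sizes, not
that the model is robust to violations of these assumptions in real data.

## Problem sizes used in checks

Parameter-recovery checks simulate two-group female cohorts (MZF + DZF
pairs) at the published female values and refit with HetACE. A rare binary
trait carries little information about the A/C split — the published
heritability interval for T2DM spans 34% to 94% — so recovered component
means stabilize slowly. The acceptance script uses 30 replicates of
1600 MZF + 1200 DZF pairs (twice the minimum stated design) with a single
data-driven optimizer start per fit; restarts were verified not to change
the optima on this design, where multimodality is mild and boundary
solutions (rA at 1 with a compensating rC) are genuine features of the
likelihood. The test suite runs reduced-size versions of the same checks
(smaller cohorts for ladder mechanics, fewer replicates for recovery), and
the stated tolerances are those of the full-size checks.

## Design decisions on open points

* The depression residualization is fit jointly on the full sample (twins
  plus singletons), not per zygosity group; with a single-sex subset the
  sex regressor drops out automatically.
* Opposite-sex pairs are stored male-first; loaders reorder on input.
* Cross-twin cross-trait descriptive correlations are mirror-pooled
  (double entry) with n counted as pairs; double-entered likelihoods use
  half weights so intervals are not artificially narrowed.
* Descriptive confidence intervals are profile-likelihood for latent
  correlations and Fisher-z for Pearson cells; none of them corrects for
  twin clustering in pooled phenotypic cells, a known limitation.
* Indeterminate biomarker status (neither HbA1c nor fasting glucose
  available) is reported as its own category, never imputed, and the
  glycemic cross-classification never feeds the genetic model, which uses
  self-report only.
* Twin pairs are simulated same-aged; the motivating design implies but
  never states this.

## Worked example

```{r example, eval = FALSE}
params <- sim_params(seed = 7)     # full five-group design, study defaults
cohort <- simulate_cohort(params)
families <- prepare_cohort(cohort)

ladder <- fit_ladder(families, restarts = 2, seed = 7)
writeLines(render_report(ladder))

sel <- ladder$fits[[ladder$selection$selected]]
variance_decomposition(sel)
profile_ci(sel, "rA_F")
```

Running the ladder on a full-size simulated cohort takes a few minutes on
one core; the two-group recovery fits used in the checks take tens of
seconds each.

## Limitations

Beyond the generator's scope above: the likelihood assumes multivariate
normal liabilities (tetrachoric-style); only two traits and ACE (no
dominance, no sibling interaction) are supported; model-selection
uncertainty is not propagated into the reported intervals; and the
missing-at-random assumption of FIML is untestable from the data alone.
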