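# twinace

Bivariate liability-threshold ACE sex-limitation models for classical twin
data, by full-information maximum likelihood.

## What problem this solves

Comorbidity between a common disease and a continuous mental-health trait —
the motivating application is self-reported type 2 diabetes (~8%
prevalence) and depression-questionnaire scores in a twin-and-singleton
cohort — can arise from shared genes, shared environment, or both. The
classical twin design separates these: monozygotic (MZ) twins share all
their segregating genes, dizygotic (DZ) twins on average half, and
comparing cross-twin correlations across zygosity and sex identifies the
contributions. twinace is for biostatisticians and behavior-genetics
researchers who need this analysis for one dichotomous plus one continuous
trait without relying on a full SEM engine, together with a synthetic
cohort generator that makes every stage testable end to end.

## The model

Each trait's variance is decomposed as A + C + E (additive genetic, common
environment, unique environment) via the bivariate Cholesky
parameterization: per sex, lower-triangular path matrices `a`, `c`, `e`
with component covariance `a a'` etc. The dichotomous trait is the
indicator of a standard-normal liability exceeding a threshold
`t_sex + beta_age (age - 43)`, with the unit-variance identification
`a11² + c11² + e11² = 1` per sex. Cross-trait overlap is summarized by the
component correlations (rA, rC, rE) and by the bridge decomposition of the
phenotypic correlation,

    r_ph = √(a²₁ a²₂) rA + √(c²₁ c²₂) rC + √(e²₁ e²₂) rE.

A family (twin pair or singleton) contributes the marginal likelihood of
its observed values: a multivariate-normal density for continuous elements
times the conditional bivariate-normal rectangle probability for the binary
elements. The sex-limitation ladder — HetACEg (free cross-sex genetic
factor correlations G in opposite-sex pairs), HetACEc (free
common-environment analogue H), HetACE (quantitative sex differences only,
G = 0.5 I, H = I), HomoACE (sexes equated) — is compared by
likelihood-ratio χ² tests and AIC = −2LL − 2df (df = observed data values −
free parameters): freeing G or H releases 4 parameters, equating sexes
removes 9.

## Worked example

```r
library(twinace)

params <- sim_params(seed = 7)          # study-scale five-group cohort
cohort   <- simulate_cohort(params)     # 842 MZ / 578 DZ / 543 DZOS pairs + 2019 singletons
families <- prepare_cohort(cohort)      # log(x+1) BDI residuals + pair assembly

ladder <- fit_ladder(families, restarts = 2, seed = 7)
writeLines(render_report(ladder))
```

```
Model fit statistics
model             -2LL       df          AIC converged
HetACE        19865.06    11867     -3868.94 yes
HetACEg       19864.32    11863     -3861.68 yes
HetACEc       19862.83    11863     -3863.17 yes
HomoACE       19891.44    11876     -3860.56 yes

Model comparisons
nested    vs reference       chi2  ddf          p       dAIC
HetACE    vs HetACEg        0.739    4     0.9465      -7.26
HetACE    vs HetACEc        2.230    4     0.6936      -5.77
HomoACE   vs HetACE        26.380    9    0.00177       8.38

Selected model: HetACE
  - qualitative genetic sex differences: chi2(4) = 0.739, p = 0.946 -> dropped
  - qualitative common-environment sex differences: chi2(4) = 2.230, p = 0.694 -> dropped
  - quantitative sex differences: chi2(9) = 26.380, p = 0.00177 -> retained (HetACE)

Standardized variance components (selected model)
  sex M, liability trait:  a2 = 69%, c2 = 28%, e2 = 3%
  sex M, continuous trait: a2 = 9%, c2 = 25%, e2 = 66%
  sex M: rA = -0.60, rC = 0.62, rE = -0.05; r_ph = 0.01 (bridges A -0.145, C 0.166, E -0.007)
  sex F, liability trait:  a2 = 89%, c2 = 1%, e2 = 11%
  sex F, continuous trait: a2 = 19%, c2 = 20%, e2 = 62%
  sex F: rA = 0.58, rC = 0.37, rE = -0.37; r_ph = 0.15 (bridges A 0.235, C 0.013, E -0.095)
```

Read this as: the qualitative constraints (the same genetic and shared-
environment factors operating in both sexes) are accepted, equating the
magnitudes across sexes is rejected, so the quantitative-sex-differences
model is retained. The generating values (the package defaults: female
liability a² = 77%, female rA = 0.53, female r_ph = 0.15) are recovered
with the sampling behavior typical of threshold traits at this cohort size:
the female side lands close (a² 89%, rA 0.58, r_ph 0.15), while the male
A/C split — the flattest direction of this likelihood — wanders along its
ridge (rA −0.60 with a compensating rC 0.62; their bridges still sum to the
small male r_ph). Single-parameter profile-likelihood intervals make that
uncertainty explicit:

```r
profile_ci(sel, "rA_F")
#> [0.26, 0.99]
```

Per-sex decompositions come from `variance_decomposition(fit)`.

A thin command-line wrapper over these functions (subcommands `sim`,
`prep`, `correlations`, `fit`, `report`) is in `inst/cli/twinace.R`.

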