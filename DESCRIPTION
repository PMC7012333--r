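Package: twinace
Title: Bivariate Liability-Threshold ACE Sex-Limitation Models for Twin Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits bivariate ACE twin models that combine a dichotomous
    liability-threshold trait (such as self-reported type 2 diabetes) with a
    continuous trait (such as log-transformed, age- and sex-regressed Beck
    Depression Inventory residuals) by full-information maximum likelihood
    over monozygotic, dizygotic, opposite-sex and singleton family units.
    Supports the classical sex-limitation model ladder (qualitative genetic,
    qualitative shared-environment, quantitative, and homogeneous models)
    with likelihood-ratio and AIC model comparison, standardized variance
    components, genetic/environmental correlations, phenotypic-correlation
    decomposition and profile-likelihood confidence intervals. Includes a
    synthetic twin-cohort generator with the exact covariance structure the
    model assumes, tetrachoric and polyserial correlation estimators, and
    phenotype preparation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
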