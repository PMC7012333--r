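# Parameter containers for the bivariate ACE sex-limitation model.
#
# A parameter set holds, per sex, lower-triangular 2x2 Cholesky path matrices
# for A (additive genetic), C (common environment) and E (unique
# environment); the cross-sex factor-correlation matrices G (genetic) and H
# (common environment) used for opposite-sex pairs; a liability threshold
# per sex with a shared age slope; and a mean for the continuous trait per
# sex. Trait 1 is the dichotomous liability trait (unit total variance
# enforced), trait 2 the continuous trait.

GROUPS_PAIR <- c("MZM", "MZF", "DZM", "DZF", "DZOS")
GROUP_SGL <- "SGL"

group_sexes <- function(group) {
  switch(group,
    MZM = c("M", "M"), MZF = c("F", "F"),
    DZM = c("M", "M"), DZF = c("F", "F"),
    DZOS = c("M", "F"),
    stop("unknown zygosity-sex group: ", group)
  )
}

#' Build Cholesky path matrices from standardized variance components
#'
#' Converts per-trait standardized proportions (a2, c2, e2) and component
#' correlations (rA, rC, rE) into the lower-triangular path matrices of the
#' bivariate Cholesky decomposition. Trait 1 is the liability trait and must
#' have unit total variance (`a2[1] + c2[1] + e2[1] = 1`); trait 2 may be
#' given a different total variance via `var2`.
#'
#' @param a2,c2,e2 Length-2 numeric vectors of standardized variance
#'   proportions (trait 1, trait 2); each trait's proportions must sum to 1.
#' @param rA,rC,rE Component correlations between the two traits, in
#'   `[-1, 1]`. A correlation must be 0 when either trait has zero variance
#'   for that component.
#' @param var2 Total variance of trait 2 (default 1).
#' @return A list with 2x2 lower-triangular matrices `a`, `c`, `e`.
#' @examples
#' p <- cholesky_from_components(a2 = c(0.77, 0.23), c2 = c(0.08, 0.13),
#'                               e2 = c(0.15, 0.64), rA = 0.53, rE = -0.24)
#' tcrossprod(p$a)  # genetic covariance matrix
#' @export
cholesky_from_components <- function(a2, c2, e2, rA = 0, rC = 0, rE = 0,
                                     var2 = 1) {
  stopifnot(length(a2) == 2, length(c2) == 2, length(e2) == 2)
  sums <- c(a2[1] + c2[1] + e2[1], a2[2] + c2[2] + e2[2])
  if (any(abs(sums - 1) > 1e-8))
    stop("standardized components must sum to 1 per trait")
  if (any(c(a2, c2, e2) < 0)) stop("variance proportions must be >= 0")
  one <- function(x2, r, label) {
    if (abs(r) > 1) stop("component correlation out of [-1, 1]: ", label)
    if (x2[1] == 0 && r != 0)
      stop("nonzero ", label, " with zero trait-1 component variance")
    x11 <- sqrt(x2[1])
    x21 <- r * sqrt(x2[2] * var2)
    x22 <- sqrt(max(0, x2[2] * var2 - x21^2))
    matrix(c(x11, x21, 0, x22), 2, 2)
  }
  list(a = one(a2, rA, "rA"), c = one(c2, rC, "rC"), e = one(e2, rE, "rE"))
}

# Solve the E-bridge so the within-person phenotypic correlation equals a
# target: r_ph = sqrt(a2_1 a2_2) rA + sqrt(c2_1 c2_2) rC + sqrt(e2_1 e2_2) rE.
re_for_rph <- function(a2, c2, e2, rA, rC, rph) {
  (rph - sqrt(a2[1] * a2[2]) * rA - sqrt(c2[1] * c2[2]) * rC) /
    sqrt(e2[1] * e2[2])
}

#' Parameters of the synthetic twin-cohort generator
#'
#' Bundles the full generating model for [simulate_cohort()]: per-sex
#' Cholesky paths, cross-sex factor correlations, liability thresholds with a
#' shared age slope, continuous-trait means, group sizes, the age
#' distribution and the seed. The defaults reproduce the study conditions of
#' the motivating cohort: 842 MZ pairs, 578 same-sex DZ pairs, 543
#' opposite-sex DZ pairs and 2019 singletons; ~8% lifetime prevalence of the
#' threshold trait; per-sex variance components at the published best-fit
#' estimates, with the component correlations not published (rC, rE) chosen
#' so the model-implied phenotypic correlations match the published 0.15
#' (female) and 0.06 (male).
#'
#' @param paths List with elements `M` and `F`, each as returned by
#'   [cholesky_from_components()]. Trait-1 paths must satisfy
#'   `a11^2 + c11^2 + e11^2 = 1` per sex.
#' @param G,H 2x2 cross-sex factor-correlation matrices for the A and C
#'   factors of opposite-sex pairs, entries in `[-1, 1]`. `G = 0.5 * I` and
#'   `H = I` give the standard DZ structure.
#' @param thresholds Named numeric `c(M = , F = )`: liability threshold
#'   intercepts at the reference age, in liability-SD units.
#' @param beta_age Threshold slope per year of age (liability SD / year),
#'   shared across sexes.
#' @param age_center Reference age (years) at which `thresholds` apply.
#' @param mu Named numeric `c(M = , F = )`: mean of the continuous trait on
#'   its latent (log) scale.
#' @param n Named integer vector of group sizes: pairs for `MZM`, `MZF`,
#'   `DZM`, `DZF`, `DZOS`, individuals for `SGL`.
#' @param age Named numeric `c(mean, sd, min, max)` for the truncated-normal
#'   age distribution.
#' @param seed Integer seed; per-group substreams are derived from it.
#' @return An object of class `c("sim_params", "ace_params")`.
#' @examples
#' p <- sim_params(n = c(MZM = 0, MZF = 50, DZM = 0, DZF = 40, DZOS = 0, SGL = 0))
#' cohort <- simulate_cohort(p)
#' @export
sim_params <- function(paths = default_paths(),
                       G = diag(2) * 0.5,
                       H = diag(2),
                       thresholds = c(M = stats::qnorm(1 - 471 / 5975),
                                      F = stats::qnorm(1 - 471 / 5975)),
                       beta_age = 0.02,
                       age_center = 43,
                       mu = c(M = 1.275, F = 1.275),
                       n = c(MZM = 421, MZF = 421, DZM = 289, DZF = 289,
                             DZOS = 543, SGL = 2019),
                       age = c(mean = 43, sd = 14.3, min = 18, max = 90),
                       seed = 1L) {
  p <- structure(list(paths = paths, G = G, H = H,
                      thresholds = thresholds, beta_age = beta_age,
                      age_center = age_center, mu = mu,
                      n = n, age = age, seed = as.integer(seed)),
                 class = c("sim_params", "ace_params"))
  validate_ace_params(p)
  if (any(p$n < 0)) stop("group sizes must be >= 0")
  if (!all(c("MZM", "MZF", "DZM", "DZF", "DZOS", "SGL") %in% names(p$n)))
    stop("n must name all of MZM, MZF, DZM, DZF, DZOS, SGL")
  if (p$age["sd"] <= 0 || p$age["min"] >= p$age["max"])
    stop("invalid age distribution")
  p
}

# Published best-fit per-sex components; rC/rE via the bridge identity so the
# implied phenotypic correlations are 0.15 (F) and 0.06 (M).
default_paths <- function() {
  a2F <- c(0.77, 0.23); c2F <- c(0.08, 0.13); e2F <- c(0.15, 0.64)
  a2M <- c(0.82, 0.07); c2M <- c(0.12, 0.22); e2M <- c(0.06, 0.71)
  list(
    M = cholesky_from_components(a2M, c2M, e2M, rA = 0.38, rC = 0,
                                 rE = re_for_rph(a2M, c2M, e2M, 0.38, 0, 0.06)),
    F = cholesky_from_components(a2F, c2F, e2F, rA = 0.53, rC = 0,
                                 rE = re_for_rph(a2F, c2F, e2F, 0.53, 0, 0.15))
  )
}

# Shared validation for model-side parameters (also used by the fitter).
validate_ace_params <- function(p) {
  for (s in c("M", "F")) {
    ps <- p$paths[[s]]
    if (is.null(ps)) stop("paths must have elements M and F")
    for (nm in c("a", "c", "e")) {
      x <- ps[[nm]]
      if (!is.matrix(x) || any(dim(x) != 2) || x[1, 2] != 0)
        stop("path matrices must be 2x2 lower-triangular")
      if (any(diag(x) < 0)) stop("diagonal path entries must be >= 0")
    }
    v1 <- ps$a[1, 1]^2 + ps$c[1, 1]^2 + ps$e[1, 1]^2
    if (abs(v1 - 1) > 1e-6)
      stop("liability variance must be 1 (a11^2+c11^2+e11^2), sex ", s)
  }
  for (nm in c("G", "H")) {
    m <- p[[nm]]
    if (!is.matrix(m) || any(dim(m) != 2) || any(abs(m) > 1 + 1e-12))
      stop(nm, " must be a 2x2 matrix with entries in [-1, 1]")
  }
  if (!all(c("M", "F") %in% names(p$thresholds)) ||
      anyNA(p$thresholds))
    stop("thresholds must be named M, F and non-missing")
  if (!is_scalar_number(p$beta_age)) stop("beta_age must be a finite scalar")
  if (!all(c("M", "F") %in% names(p$mu)) || !all(is.finite(p$mu)))
    stop("mu must be finite and named M, F")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Synthetic twin-cohort parameters\n")
  cat("  pairs:", paste(names(x$n), x$n, sep = "=", collapse = " "), "\n")
  cat("  thresholds (M, F):", round(x$thresholds[["M"]], 3),
      round(x$thresholds[["F"]], 3),
      " age slope:", x$beta_age, "/yr (centered at", x$age_center, "y)\n")
  for (s in c("M", "F")) {
    std <- standardize_paths(x$paths[[s]])
    cat(sprintf("  %s: a2 = (%.2f, %.2f)  c2 = (%.2f, %.2f)  e2 = (%.2f, %.2f)\n",
                s, std["A", 1], std["A", 2], std["C", 1], std["C", 2],
                std["E", 1], std["E", 2]))
  }
  invisible(x)
}

# ---- flat key-value config ------------------------------------------------

.config_path_keys <- function(sex) {
  s <- tolower(sex)
  unlist(lapply(c("a", "c", "e"), function(x)
    paste0(x, c("11", "21", "22"), "_", s)))
}

#' Read or write generator parameters as a flat key-value config
#'
#' The schema is flat YAML: per-sex path entries `a11_m, a21_m, a22_m, c11_m,
#' ..., e22_f`; cross-sex factor correlations `g11, g12, g21, g22, h11, ...`;
#' `t_m, t_f, beta_age, age_center, mu_m, mu_f`; group sizes `n_mzm, n_mzf,
#' n_dzm, n_dzf, n_dzos, n_sgl`; `age_mean, age_sd, age_min, age_max`; and
#' `seed`.
#'
#' @param path File path.
#' @param params A [sim_params()] object (for writing).
#' @return `read_sim_config()` returns a [sim_params()] object;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  kv <- yaml::read_yaml(path)
  grab <- function(keys) vapply(keys, function(k) {
    if (is.null(kv[[k]])) stop("config missing key: ", k)
    as.numeric(kv[[k]])
  }, numeric(1))
  paths <- lapply(c(M = "M", F = "F"), function(s) {
    v <- grab(.config_path_keys(s))
    lt <- function(i) matrix(c(v[i], v[i + 1], 0, v[i + 2]), 2, 2)
    list(a = lt(1), c = lt(4), e = lt(7))
  })
  sim_params(
    paths = paths,
    G = matrix(grab(c("g11", "g21", "g12", "g22")), 2, 2),
    H = matrix(grab(c("h11", "h21", "h12", "h22")), 2, 2),
    thresholds = c(M = grab("t_m")[[1]], F = grab("t_f")[[1]]),
    beta_age = grab("beta_age")[[1]],
    age_center = grab("age_center")[[1]],
    mu = c(M = grab("mu_m")[[1]], F = grab("mu_f")[[1]]),
    n = c(MZM = grab("n_mzm")[[1]], MZF = grab("n_mzf")[[1]],
          DZM = grab("n_dzm")[[1]], DZF = grab("n_dzf")[[1]],
          DZOS = grab("n_dzos")[[1]], SGL = grab("n_sgl")[[1]]),
    age = c(mean = grab("age_mean")[[1]], sd = grab("age_sd")[[1]],
            min = grab("age_min")[[1]], max = grab("age_max")[[1]]),
    seed = grab("seed")[[1]]
  )
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  kv <- list()
  for (s in c("M", "F")) {
    keys <- .config_path_keys(s)
    vals <- unlist(lapply(c("a", "c", "e"), function(x)
      params$paths[[s]][[x]][c(1, 2, 4)]))
    kv[keys] <- as.list(unname(vals))
  }
  kv[c("g11", "g21", "g12", "g22")] <- as.list(as.vector(params$G))
  kv[c("h11", "h21", "h12", "h22")] <- as.list(as.vector(params$H))
  kv$t_m <- unname(params$thresholds[["M"]])
  kv$t_f <- unname(params$thresholds[["F"]])
  kv$beta_age <- params$beta_age
  kv$age_center <- params$age_center
  kv$mu_m <- unname(params$mu[["M"]])
  kv$mu_f <- unname(params$mu[["F"]])
  for (g in names(params$n)) kv[[paste0("n_", tolower(g))]] <- unname(params$n[[g]])
  kv$age_mean <- unname(params$age[["mean"]])
  kv$age_sd <- unname(params$age[["sd"]])
  kv$age_min <- unname(params$age[["min"]])
  kv$age_max <- unname(params$age[["max"]])
  kv$seed <- params$seed
  yaml::write_yaml(kv, path, precision = 15)
  invisible(path)
}
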