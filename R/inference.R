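# Standardized variance components, component correlations, the
# phenotypic-correlation decomposition, and profile-likelihood intervals.

#' Standardized variance components from Cholesky paths
#'
#' For each trait j, the standardized component is
#' `(X X')_jj / (A A' + C C' + E E')_jj` for component path matrix X, so the
#' three proportions sum to 1 per trait.
#'
#' @param paths A list with 2x2 lower-triangular matrices `a`, `c`, `e`
#'   (one sex's `CholeskySet`).
#' @return A 3x2 matrix, rows `A`, `C`, `E`, columns traits 1 and 2.
#' @examples
#' p <- cholesky_from_components(c(0.36, 0), c(0, 0), c(0.64, 1))
#' standardize_paths(p)["A", 1]  # 0.36
#' @export
standardize_paths <- function(paths) {
  SA <- tcrossprod(paths$a)
  SC <- tcrossprod(paths$c)
  SE <- tcrossprod(paths$e)
  tot <- diag(SA + SC + SE)
  if (any(tot <= 0)) stop("zero total variance for a trait")
  out <- rbind(A = diag(SA) / tot, C = diag(SC) / tot, E = diag(SE) / tot)
  colnames(out) <- c("trait1", "trait2")
  out
}

#' Correlation between the two traits' A, C or E factors
#'
#' `r_X = (X X')_12 / sqrt((X X')_11 (X X')_22)`; in the bivariate Cholesky
#' this equals `x21 / sqrt(x21^2 + x22^2)` (times the sign of `x11`).
#' Undefined (NA with attribute `"undefined"`) when either trait has zero
#' variance for the component.
#'
#' @param paths One sex's path list (`a`, `c`, `e` matrices).
#' @param component `"A"`, `"C"` or `"E"`.
#' @return The component correlation, or NA if undefined.
#' @export
component_correlation <- function(paths, component = c("A", "C", "E")) {
  component <- match.arg(component)
  X <- tcrossprod(paths[[tolower(component)]])
  if (X[1, 1] <= 0 || X[2, 2] <= 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  X[1, 2] / sqrt(X[1, 1] * X[2, 2])
}

#' Decompose the phenotypic correlation into A, C, E bridges
#'
#' Each component contributes `sqrt(x2_trait1 * x2_trait2) * r_X` to the
#' within-person cross-trait correlation; the bridges sum to r_ph.
#'
#' @param std 3x2 matrix of standardized components ([standardize_paths()]).
#' @param rA,rC,rE Component correlations (NA treated as a zero bridge from
#'   a zero-variance component).
#' @return Named vector with `A`, `C`, `E` bridges and `r_ph`.
#' @export
decompose_rph <- function(std, rA, rC, rE) {
  bridge <- function(row, r) {
    if (is.na(r)) 0 else sqrt(std[row, 1] * std[row, 2]) * r
  }
  b <- c(A = bridge("A", rA), C = bridge("C", rC), E = bridge("E", rE))
  c(b, r_ph = sum(b))
}

#' Full variance decomposition of a fitted model
#'
#' Standardized a2/c2/e2 per trait, component correlations and the
#' phenotypic-correlation decomposition for each sex in the fit.
#'
#' @param fit An `ace_fit`.
#' @return A list of class `ace_decomposition`, one element per sex, each
#'   with `components` (3x2), `rA`, `rC`, `rE`, `bridges`.
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "ace_fit"))
  if (is.null(fit$params)) stop("fit did not converge; no parameters")
  out <- lapply(stats::setNames(fit$sexes, fit$sexes), function(s) {
    paths <- fit$params$paths[[s]]
    std <- standardize_paths(paths)
    rA <- component_correlation(paths, "A")
    rC <- component_correlation(paths, "C")
    rE <- component_correlation(paths, "E")
    list(components = std, rA = rA, rC = rC, rE = rE,
         bridges = decompose_rph(std, rA, rC, rE))
  })
  structure(out, class = "ace_decomposition")
}

#' @export
print.ace_decomposition <- function(x, ...) {
  for (s in names(x)) {
    d <- x[[s]]
    cat("Sex", s, "\n")
    cat(sprintf("  trait 1 (liability):  a2 = %3.0f%%  c2 = %3.0f%%  e2 = %3.0f%%\n",
                100 * d$components["A", 1], 100 * d$components["C", 1],
                100 * d$components["E", 1]))
    cat(sprintf("  trait 2 (continuous): a2 = %3.0f%%  c2 = %3.0f%%  e2 = %3.0f%%\n",
                100 * d$components["A", 2], 100 * d$components["C", 2],
                100 * d$components["E", 2]))
    cat(sprintf("  rA = %.2f  rC = %.2f  rE = %.2f  r_ph = %.2f\n",
                d$rA, d$rC, d$rE, d$bridges["r_ph"]))
  }
  invisible(x)
}

# ---- profile likelihood ---------------------------------------------------

#' Profile-likelihood interval for one coordinate of an objective
#'
#' Finds the two values of coordinate `index` at which the profile -2LL
#' (re-optimizing all other coordinates) rises by the chi-square(1) quantile
#' above its minimum. The search steps outward from the optimum using a
#' curvature-based step, then brackets each crossing with [stats::uniroot()].
#' Intervals are censored at the box bounds (reported one-sided via the
#' `"boundary"` attribute).
#'
#' @param objective Function mapping the full parameter vector to -2LL.
#' @param par Parameter vector at the optimum.
#' @param index Coordinate to profile.
#' @param lower,upper Box bounds (vectors or scalars recycled).
#' @param level Confidence level (default 0.95).
#' @param m2ll_min Objective value at `par` (computed if omitted).
#' @return Numeric `c(low, high)` with attribute `"boundary"` (logical 2).
#' @export
profile_interval <- function(objective, par, index, lower, upper,
                             level = 0.95, m2ll_min = NULL) {
  n <- length(par)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  f0 <- m2ll_min %||% objective(par)
  crit <- stats::qchisq(level, 1)
  target <- f0 + crit
  prof <- local({
    warm <- par
    function(v) {
      if (n == 1) return(objective(v))
      x <- warm
      x[index] <- v
      res <- stats::optim(x[-index], function(z) {
        y <- numeric(n)
        y[index] <- v
        y[-index] <- z
        objective(y)
      }, method = "L-BFGS-B", lower = lower[-index], upper = upper[-index],
      control = list(factr = 1e6, ndeps = rep(1e-5, n - 1)))
      w <- numeric(n)
      w[index] <- v
      w[-index] <- res$par
      warm <<- w
      res$value
    }
  })
  # curvature-based initial step
  h <- max(1e-4, 1e-3 * (upper[index] - lower[index]) / 2)
  vhat <- par[index]
  f_p <- prof(min(vhat + h, upper[index]))
  f_m <- prof(max(vhat - h, lower[index]))
  d2 <- max((f_p - 2 * f0 + f_m) / h^2, 1e-6)
  se <- sqrt(2 / d2)
  bound_flag <- c(FALSE, FALSE)
  one_side <- function(dir) {
    bound <- if (dir > 0) upper[index] else lower[index]
    v_in <- vhat
    f_in <- f0
    step <- dir * 0.7 * se
    for (k in 1:40) {
      v_try <- v_in + step
      hit_bound <- (dir > 0 && v_try >= bound) || (dir < 0 && v_try <= bound)
      if (hit_bound) v_try <- bound
      f_try <- prof(v_try)
      if (is.finite(f_try) && f_try >= target) {
        root <- stats::uniroot(function(v) prof(v) - target,
                               lower = min(v_in, v_try),
                               upper = max(v_in, v_try),
                               tol = 1e-4 * max(se, 1e-3))$root
        return(root)
      }
      if (hit_bound) {
        bound_flag[if (dir > 0) 2 else 1] <<- TRUE
        return(bound)
      }
      v_in <- v_try
      step <- step * 1.6
    }
    bound_flag[if (dir > 0) 2 else 1] <<- TRUE
    bound
  }
  lo <- one_side(-1)
  hi <- one_side(+1)
  out <- c(lo, hi)
  attr(out, "boundary") <- bound_flag
  out
}

# user-facing parameter names -> internal coordinate + monotone transform
.profile_alias <- function(fit, parameter) {
  nm <- parameter
  sfx <- ""
  if (grepl("_[MF]$", nm)) {
    sfx <- paste0("_", tolower(sub(".*_", "", nm)))
    nm <- sub("_[MF]$", "", nm)
  }
  direct <- c(rA = "ra", rC = "rc", rE = "re", threshold = "t", mu = "mu",
              beta_age = "beta")
  if (nm %in% names(direct)) {
    coord <- if (nm == "beta_age") "beta" else paste0(direct[[nm]], sfx)
    return(list(coord = coord, transform = identity))
  }
  if (nm == "a2_liability") {
    return(list(coord = paste0("th1", sfx),
                transform = function(v) cos(v)^2))
  }
  if (parameter %in% fit$layout$name)
    return(list(coord = parameter, transform = identity))
  stop("unsupported parameter for profiling: ", parameter,
       " (free coordinates: ", paste(fit$layout$name, collapse = ", "), ")")
}

#' Profile-likelihood confidence interval for a fitted parameter
#'
#' Supported parameters: any free internal coordinate of the fit by name,
#' plus the aliases `"rA_F"`, `"rA_M"`, `"rC_*"`, `"rE_*"` (component
#' correlations), `"a2_liability_F"`/`"a2_liability_M"` (trait-1
#' heritability, profiled through its monotone angle parameterization),
#' `"threshold_M"/"_F"`, `"mu_M"/"_F"` and `"beta_age"`. For HomoACE fits
#' use the un-suffixed names (`"rA"`, ...).
#'
#' @param fit A converged `ace_fit`.
#' @param parameter Parameter name (see Details).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)` on the parameter's natural scale, with
#'   attribute `"boundary"`.
#' @export
profile_ci <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "ace_fit"))
  if (!fit$converged || is.null(fit$par))
    stop("profile CI requires a converged fit")
  al <- .profile_alias(fit, parameter)
  idx <- match(al$coord, fit$layout$name)
  if (is.na(idx)) stop("coordinate not free in this fit: ", al$coord)
  ci <- profile_interval(fit$objective, unname(fit$par), idx,
                         fit$layout$lower, fit$layout$upper, level,
                         m2ll_min = fit$minus2ll)
  bd <- attr(ci, "boundary")
  out <- sort(al$transform(ci))
  attr(out, "boundary") <- bd
  out
}
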