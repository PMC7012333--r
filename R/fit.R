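# Maximum-likelihood fitting of the sex-limitation model ladder.
#
# Four variants:
#   HetACEg - sex-specific paths, free cross-sex genetic factor correlations
#             (G; 4 free entries) in opposite-sex pairs, H fixed at I
#   HetACEc - sex-specific paths, free cross-sex common-environment factor
#             correlations (H; 4 free entries), G fixed at 0.5 I
#   HetACE  - sex-specific paths (quantitative sex differences only),
#             G = 0.5 I and H = I
#   HomoACE - all nine path parameters equated across sexes
# Thresholds and continuous-trait means stay sex-specific in all variants;
# the age slope on the threshold is shared.
#
# The unit liability variance (a11^2 + c11^2 + e11^2 = 1 per sex) is imposed
# by a spherical reparameterization of the three trait-1 paths during
# optimization, but the three paths are counted as estimated parameters
# (with the constraint counted separately), which is the convention under
# which equating sexes releases 9 parameters and freeing G or H releases 4.

MODEL_VARIANTS <- c("HetACEg", "HetACEc", "HetACE", "HomoACE")

variant_flags <- function(variant) {
  variant <- match.arg(variant, MODEL_VARIANTS)
  list(variant = variant,
       free_G = variant == "HetACEg",
       free_H = variant == "HetACEc",
       equate_sexes = variant == "HomoACE")
}

#' Canonical free-parameter count of a model variant
#'
#' Counts estimated parameters for the full two-sex, five-group design:
#' per-sex Cholesky paths (9 per sex, equated under HomoACE), two
#' thresholds, two continuous-trait means, one shared age slope, and the
#' free cross-sex factor correlations (4) under HetACEg or HetACEc.
#'
#' @param variant One of `"HetACEg"`, `"HetACEc"`, `"HetACE"`, `"HomoACE"`.
#' @return Integer count.
#' @examples
#' count_free_params("HetACEg") - count_free_params("HetACE")  # 4
#' count_free_params("HetACE") - count_free_params("HomoACE")  # 9
#' @export
count_free_params <- function(variant) {
  fl <- variant_flags(variant)
  paths <- if (fl$equate_sexes) 9L else 18L
  paths + 2L + 2L + 1L + (if (fl$free_G) 4L else 0L) +
    (if (fl$free_H) 4L else 0L)
}

#' Akaike information criterion from -2LL and degrees of freedom
#'
#' Uses the observed-statistics convention `AIC = -2LL - 2 df`, where
#' `df = (number of non-missing observed data values) - (free parameters)`.
#'
#' @param minus2ll Minus twice the maximized log-likelihood.
#' @param df Degrees of freedom.
#' @return The AIC (scalar).
#' @examples
#' aic(15429.91, 7799)  # -168.09
#' @export
aic <- function(minus2ll, df) {
  stopifnot(is.finite(minus2ll), is.finite(df))
  minus2ll - 2 * df
}

# ---- internal parameter layout -------------------------------------------

.path_par_names <- c("th1", "th2", "sa", "ra", "sc", "rc", "se", "re")

# Layout rows: name, lower, upper, start. `sexes` is the set present in the
# data; under HomoACE path parameters are shared (no suffix).
par_layout <- function(flags, sexes, has_dzos, start) {
  rows <- list()
  add <- function(name, lower, upper, st)
    rows[[length(rows) + 1]] <<- data.frame(name = name, lower = lower,
                                            upper = upper, start = st)
  path_block <- function(sfx, v2) {
    s3 <- sqrt(max(v2, 1e-4) / 3)
    add(paste0("th1", sfx), 0.02, pi / 2 - 0.02, acos(sqrt(1 / 3)))
    add(paste0("th2", sfx), 0.02, pi / 2 - 0.02, pi / 4)
    for (comp in c("a", "c", "e")) {
      add(paste0("s", comp, sfx), 1e-3, 5, s3)
      add(paste0("r", comp, sfx), -0.995, 0.995, 0)
    }
  }
  suffixes <- if (flags$equate_sexes) "" else paste0("_", tolower(sexes))
  if (flags$equate_sexes) {
    path_block("", mean(unlist(start$v2[sexes])))
  } else {
    for (i in seq_along(sexes)) path_block(suffixes[i], start$v2[[sexes[i]]])
  }
  for (s in sexes) {
    add(paste0("t_", tolower(s)), -3.5, 3.5, start$t[[s]])
    add(paste0("mu_", tolower(s)), -10, 10, start$mu[[s]])
  }
  add("beta", -0.3, 0.3, 0.01)
  if (flags$free_G && has_dzos)
    for (nm in c("g11", "g21", "g12", "g22"))
      add(nm, -0.995, 0.995, if (nm %in% c("g11", "g22")) 0.5 else 0)
  if (flags$free_H && has_dzos)
    for (nm in c("h11", "h21", "h12", "h22"))
      add(nm, -0.995, 0.995, if (nm %in% c("h11", "h22")) 1 - 1e-3 else 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Data-driven starting values.
start_values <- function(tf) {
  w <- tf$wide
  sex_of <- function(col_sex, col) stats::setNames(w[[col]], w[[col_sex]])
  d_all <- c(stats::setNames(w$d1, w$sex1), stats::setNames(w$d2, w$sex2))
  y_all <- c(stats::setNames(w$y1, w$sex1), stats::setNames(w$y2, w$sex2))
  out <- list(t = list(), mu = list(), v2 = list())
  for (s in c("M", "F")) {
    ds <- d_all[names(d_all) == s & !is.na(d_all)]
    ys <- y_all[names(y_all) == s & !is.na(y_all)]
    p <- if (length(ds)) mean(ds) else 0.1
    p <- min(max(p, 1 / (length(ds) + 2)), 1 - 1 / (length(ds) + 2))
    out$t[[s]] <- min(max(stats::qnorm(1 - p), -3), 3)
    out$mu[[s]] <- if (length(ys)) mean(ys) else 0
    out$v2[[s]] <- if (length(ys) > 1) stats::var(ys) else 1
  }
  out
}

# Rebuild an ace_params object from the internal vector.
build_params <- function(x, layout, flags, sexes) {
  v <- stats::setNames(x, layout$name)
  path_from <- function(sfx) {
    th1 <- v[[paste0("th1", sfx)]]
    th2 <- v[[paste0("th2", sfx)]]
    first <- c(a = cos(th1), c = sin(th1) * cos(th2), e = sin(th1) * sin(th2))
    out <- list()
    for (comp in c("a", "c", "e")) {
      s2 <- v[[paste0("s", comp, sfx)]]
      r2 <- v[[paste0("r", comp, sfx)]]
      out[[comp]] <- matrix(c(first[[comp]], r2 * s2, 0,
                              s2 * sqrt(1 - r2^2)), 2, 2)
    }
    out
  }
  paths <- list()
  if (flags$equate_sexes) {
    shared <- path_from("")
    paths <- list(M = shared, F = shared)
  } else {
    for (s in c("M", "F"))
      paths[[s]] <- if (s %in% sexes) path_from(paste0("_", tolower(s)))
        else path_from(paste0("_", tolower(sexes[1])))
  }
  gv <- function(nm, def) if (nm %in% layout$name) v[[nm]] else def
  G <- matrix(c(gv("g11", 0.5), gv("g21", 0), gv("g12", 0), gv("g22", 0.5)),
              2, 2)
  H <- matrix(c(gv("h11", 1), gv("h21", 0), gv("h12", 0), gv("h22", 1)), 2, 2)
  thr <- c(M = gv("t_m", 1.5), F = gv("t_f", 1.5))
  mu <- c(M = gv("mu_m", 0), F = gv("mu_f", 0))
  structure(list(paths = paths, G = G, H = H, thresholds = thr,
                 beta_age = v[["beta"]], age_center = 43, mu = mu),
            class = "ace_params")
}

.sexes_in_data <- function(tf) {
  w <- tf$wide
  intersect(c("M", "F"), unique(c(w$sex1, w$sex2[!is.na(w$sex2)])))
}

# ---- fitting --------------------------------------------------------------

#' Fit one sex-limitation model variant by FIML
#'
#' Maximizes the joint ordinal-continuous likelihood under the variant's
#' constraint map with bound-constrained quasi-Newton optimization
#' (L-BFGS-B) over a reparameterized vector that enforces the unit liability
#' variance. Multiple jittered starts guard against the mild multimodality
#' of threshold-model likelihoods; the best converged start is kept. If all
#' starts fail the fit is returned with `converged = FALSE` rather than
#' raising.
#'
#' @param data A `twin_families` object or a cohort data.frame.
#' @param variant `"HetACEg"`, `"HetACEc"`, `"HetACE"`, or `"HomoACE"`.
#' @param restarts Total number of starts (first from data-driven starting
#'   values, the rest jittered). Default 5.
#' @param seed Optional integer seed controlling the jitter.
#' @param extra_starts Optional list of named numeric vectors used as
#'   additional warm starts (e.g. a nested model's solution).
#' @param control Optional list: `factr`, `maxit`, `ndeps` forwarded to
#'   [stats::optim()]'s L-BFGS-B.
#' @return An object of class `ace_fit`.
#' @export
fit_ace <- function(data, variant, restarts = 5, seed = NULL,
                    extra_starts = NULL, control = list()) {
  if (!inherits(data, "twin_families")) data <- prepare_cohort(data)
  if (nrow(data$wide) == 0) stop("empty data")
  flags <- variant_flags(variant)
  blocks <- compile_blocks(data)
  sexes <- .sexes_in_data(data)
  groups <- unique(data$wide$group)
  if (length(setdiff(groups, GROUP_SGL)) < 2)
    warning("fewer than 2 zygosity groups: A and C are not separately identified")
  has_dzos <- "DZOS" %in% groups
  if ((flags$free_G || flags$free_H) && !has_dzos) {
    warning("no opposite-sex pairs: cross-sex factor correlations are not ",
            "identified and stay fixed")
    flags$free_G <- flags$free_H <- FALSE
  }
  if (length(sexes) == 1 && flags$equate_sexes)
    flags$equate_sexes <- FALSE  # nothing to equate; same layout as HetACE
  layout <- par_layout(flags, sexes, has_dzos, start_values(data))
  objective <- function(x) {
    val <- tryCatch({
      p <- build_params(x, layout, flags, sexes)
      -2 * sum(vapply(blocks, block_loglik, numeric(1), params = p,
                      warn_underflow = FALSE))
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  n_par <- nrow(layout)
  ctl <- list(factr = control$factr %||% 1e6,
              maxit = control$maxit %||% 500,
              ndeps = rep(control$ndeps %||% 1e-5, n_par))
  starts <- list(layout$start)
  for (es in extra_starts %||% list()) {
    st <- layout$start
    m <- match(layout$name, names(es))
    st[!is.na(m)] <- es[m[!is.na(m)]]
    starts[[length(starts) + 1]] <- pmin(pmax(st, layout$lower + 1e-6),
                                         layout$upper - 1e-6)
  }
  if (!is.null(seed)) set.seed(seed)
  n_jitter <- max(0, restarts - 1)
  for (j in seq_len(n_jitter)) {
    st <- layout$start + stats::rnorm(n_par, 0, 0.2)
    starts[[length(starts) + 1]] <- pmin(pmax(st, layout$lower + 1e-6),
                                         layout$upper - 1e-6)
  }
  best <- NULL
  n_used <- 0
  for (st in starts) {
    n_used <- n_used + 1
    res <- tryCatch(
      stats::optim(st, objective, method = "L-BFGS-B",
                   lower = layout$lower, upper = layout$upper,
                   control = ctl),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  converged <- !is.null(best) && best$convergence %in% c(0L, 1L)
  w <- data$wide
  n_obs <- sum(!is.na(c(w$d1, w$d2))) + sum(!is.na(c(w$y1, w$y2)))
  n_path_sets <- if (flags$equate_sexes) 1L else length(sexes)
  n_free <- n_par + n_path_sets  # +1 per path set: constraint convention
  m2ll <- if (is.null(best)) Inf else best$value
  df <- n_obs - n_free
  structure(list(
    variant = flags$variant,
    params = if (is.null(best)) NULL
      else build_params(best$par, layout, flags, sexes),
    par = if (is.null(best)) NULL else stats::setNames(best$par, layout$name),
    layout = layout, flags = flags, sexes = sexes,
    minus2ll = m2ll, df = df, n_free_params = n_free,
    n_observed_statistics = n_obs,
    aic = if (is.finite(m2ll)) aic(m2ll, df) else NA_real_,
    converged = converged, n_restarts_used = n_used,
    objective = objective, data = data
  ), class = "ace_fit")
}

#' @export
print.ace_fit <- function(x, digits = 2, ...) {
  cat(sprintf("%s fit: -2LL = %.*f, df = %d, AIC = %.*f%s\n",
              x$variant, digits, x$minus2ll, x$df, digits, x$aic,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$params)) {
    for (s in x$sexes) {
      std <- standardize_paths(x$params$paths[[s]])
      cat(sprintf("  %s: a2 = (%.0f%%, %.0f%%)  c2 = (%.0f%%, %.0f%%)  e2 = (%.0f%%, %.0f%%)  rA = %.2f\n",
                  s, 100 * std["A", 1], 100 * std["A", 2],
                  100 * std["C", 1], 100 * std["C", 2],
                  100 * std["E", 1], 100 * std["E", 2],
                  component_correlation(x$params$paths[[s]], "A")))
    }
  }
  invisible(x)
}

# ---- model comparison -----------------------------------------------------

.NESTING <- list(
  HomoACE = c("HetACE", "HetACEg", "HetACEc"),
  HetACE = c("HetACEg", "HetACEc")
)

#' Likelihood-ratio and AIC comparison of two nested fits
#'
#' The chi-square statistic is the difference in -2LL between the nested
#' (more constrained) and reference (richer) model, tested on the difference
#' in free-parameter counts.
#'
#' @param nested,reference `ace_fit` objects (or lists with `variant`,
#'   `minus2ll`, `df`, `aic`).
#' @return A one-row data.frame (`ComparisonRow`): `nested`, `reference`,
#'   `chi2`, `delta_df`, `p_value`, `delta_aic`.
#' @export
compare_fits <- function(nested, reference) {
  if (!reference$variant %in% (.NESTING[[nested$variant]] %||% character(0)))
    stop(nested$variant, " is not nested in ", reference$variant)
  chi2 <- nested$minus2ll - reference$minus2ll
  delta_df <- nested$df - reference$df
  if (delta_df <= 0) stop("reference must have more free parameters")
  data.frame(nested = nested$variant, reference = reference$variant,
             chi2 = chi2, delta_df = delta_df,
             p_value = stats::pchisq(max(0, chi2), delta_df,
                                     lower.tail = FALSE),
             delta_aic = nested$aic - reference$aic,
             stringsAsFactors = FALSE)
}

#' Select the best-fitting model from the sex-limitation ladder
#'
#' Applies the published decision procedure: a constraint is accepted (the
#' more parsimonious model preferred) when its likelihood-ratio test is
#' non-significant at `alpha` or when the AIC favors the parsimonious model
#' by at least `aic_margin`; otherwise the richer model is retained. The
#' qualitative tests (HetACEg and HetACEc against HetACE) are evaluated
#' first, then the quantitative test (HomoACE against HetACE).
#'
#' @param comparisons A data.frame of comparison rows ([compare_fits()]),
#'   or a single `ace_fit` (returned unchanged).
#' @param alpha Significance level for the ladder decisions (default 0.05).
#' @param aic_margin AIC difference giving substantial support to the more
#'   parsimonious model (default 10).
#' @return A list of class `ace_selection` with `selected` (variant name)
#'   and `trail` (character decision log).
#' @export
select_best <- function(comparisons, alpha = 0.05, aic_margin = 10) {
  if (inherits(comparisons, "ace_fit")) {
    return(structure(list(selected = comparisons$variant,
                          trail = "single model supplied; returned unchanged"),
                     class = "ace_selection"))
  }
  cmp <- comparisons
  row_for <- function(nested, reference) {
    i <- which(cmp$nested == nested & cmp$reference == reference)
    if (length(i)) cmp[i[1], ] else NULL
  }
  trail <- character(0)
  accept <- function(row) {
    # constraint accepted if non-significant or AIC margin favors parsimony
    row$p_value >= alpha || row$delta_aic <= -aic_margin
  }
  keep_g <- FALSE
  keep_c <- FALSE
  rg <- row_for("HetACE", "HetACEg")
  if (!is.null(rg)) {
    keep_g <- !accept(rg)
    trail <- c(trail, sprintf(
      "qualitative genetic sex differences: chi2(%d) = %.3f, p = %.3g -> %s",
      rg$delta_df, rg$chi2, rg$p_value,
      if (keep_g) "retained (HetACEg)" else "dropped"))
  }
  rc <- row_for("HetACE", "HetACEc")
  if (!is.null(rc)) {
    keep_c <- !accept(rc)
    trail <- c(trail, sprintf(
      "qualitative common-environment sex differences: chi2(%d) = %.3f, p = %.3g -> %s",
      rc$delta_df, rc$chi2, rc$p_value,
      if (keep_c) "retained (HetACEc)" else "dropped"))
  }
  if (keep_g && keep_c) {
    return(structure(list(selected = "HetACEg+HetACEc", trail = c(trail,
      "both qualitative effects significant; models flagged jointly")),
      class = "ace_selection"))
  }
  if (keep_g || keep_c) {
    sel <- if (keep_g) "HetACEg" else "HetACEc"
    return(structure(list(selected = sel, trail = trail),
                     class = "ace_selection"))
  }
  rh <- row_for("HomoACE", "HetACE")
  if (is.null(rh)) {
    return(structure(list(selected = "HetACE", trail = c(trail,
      "no quantitative comparison supplied; HetACE retained")),
      class = "ace_selection"))
  }
  homo <- accept(rh)
  trail <- c(trail, sprintf(
    "quantitative sex differences: chi2(%d) = %.3f, p = %.3g -> %s",
    rh$delta_df, rh$chi2, rh$p_value,
    if (homo) "equated (HomoACE)" else "retained (HetACE)"))
  structure(list(selected = if (homo) "HomoACE" else "HetACE", trail = trail),
            class = "ace_selection")
}

#' @export
print.ace_selection <- function(x, ...) {
  cat("Selected model:", x$selected, "\n")
  for (t in x$trail) cat(" -", t, "\n")
  invisible(x)
}

#' Fit the full sex-limitation ladder and select the best model
#'
#' Fits HetACE first, warm-starts the richer qualitative models (HetACEg,
#' HetACEc) and the equated model (HomoACE) from its solution, builds the
#' three ladder comparisons and applies [select_best()].
#'
#' @inheritParams fit_ace
#' @param alpha,aic_margin Passed to [select_best()].
#' @return A list of class `ace_ladder`: `fits` (named list), `comparisons`
#'   (data.frame), `selection` (`ace_selection`).
#' @export
fit_ladder <- function(data, restarts = 5, seed = NULL, alpha = 0.05,
                       aic_margin = 10, control = list()) {
  if (!inherits(data, "twin_families")) data <- prepare_cohort(data)
  fits <- list()
  fits$HetACE <- fit_ace(data, "HetACE", restarts = restarts, seed = seed,
                         control = control)
  warm <- list(fits$HetACE$par)
  fits$HetACEg <- fit_ace(data, "HetACEg", restarts = restarts, seed = seed,
                          extra_starts = warm, control = control)
  fits$HetACEc <- fit_ace(data, "HetACEc", restarts = restarts, seed = seed,
                          extra_starts = warm, control = control)
  homo_start <- collapse_start(fits$HetACE)
  fits$HomoACE <- fit_ace(data, "HomoACE", restarts = restarts, seed = seed,
                          extra_starts = list(homo_start), control = control)
  pairs <- list(c("HetACE", "HetACEg"), c("HetACE", "HetACEc"),
                c("HomoACE", "HetACE"))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    # degenerate layouts (single sex, no opposite-sex pairs) can make a
    # nominal nesting vacuous; skip those rows
    tryCatch(compare_fits(fits[[pr[1]]], fits[[pr[2]]]),
             error = function(e) NULL)
  }))
  structure(list(fits = fits, comparisons = comparisons,
                 selection = select_best(comparisons, alpha, aic_margin)),
            class = "ace_ladder")
}

# Average the two sexes' path parameters as a HomoACE warm start.
collapse_start <- function(fit) {
  if (is.null(fit$par)) return(numeric(0))
  v <- fit$par
  out <- c()
  for (nm in .path_par_names) {
    vals <- v[paste0(nm, c("_m", "_f"))]
    vals <- vals[!is.na(vals)]
    if (length(vals)) out[nm] <- mean(vals)
  }
  keep <- intersect(names(v), c("t_m", "t_f", "mu_m", "mu_f", "beta"))
  c(out, v[keep])
}

#' @export
print.ace_ladder <- function(x, ...) {
  for (f in x$fits) print(f, ...)
  cat("\n")
  print(x$comparisons, row.names = FALSE)
  cat("\n")
  print(x$selection)
  invisible(x)
}
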