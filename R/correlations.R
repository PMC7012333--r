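# Latent and product-moment correlations for twin descriptives.

new_cor_estimate <- function(r, ci, kind, n, boundary = FALSE, low_n = FALSE) {
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2], kind = kind,
                 n = n, boundary = boundary, low_n = low_n),
            class = "cor_estimate")
}

#' @export
print.cor_estimate <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f [%.3f, %.3f], n = %s%s%s\n",
              x$kind, x$r, x$ci_low, x$ci_high, format(x$n),
              if (x$boundary) " (boundary)" else "",
              if (x$low_n) " (low n)" else ""))
  invisible(x)
}

# Profile-deviance CI for a 1-d latent correlation on (-1, 1).
# loglik: vectorized in r is not required; called pointwise.
.profile_ci_r <- function(loglik, rhat, level, lim = 0.9999) {
  crit <- stats::qchisq(level, 1)
  ll0 <- loglik(rhat)
  dev <- function(r) 2 * (ll0 - loglik(r))
  boundary <- FALSE
  lo <- if (dev(-lim) <= crit) {
    boundary <- TRUE
    -1
  } else {
    stats::uniroot(function(r) dev(r) - crit, lower = -lim, upper = rhat,
                   tol = 1e-6)$root
  }
  hi <- if (dev(lim) <= crit) {
    boundary <- TRUE
    1
  } else {
    stats::uniroot(function(r) dev(r) - crit, lower = rhat, upper = lim,
                   tol = 1e-6)$root
  }
  list(ci = c(lo, hi), boundary = boundary)
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Maximum-likelihood correlation of a latent bivariate normal, with
#' thresholds fixed at the inverse-normal of the margins; the confidence
#' interval is profile-likelihood. Rows index the first variable (0, 1),
#' columns the second. Non-integer (weighted) counts are allowed.
#'
#' @param tab 2x2 matrix of counts; all margins must be nonzero.
#' @param conf_level Confidence level (default 0.95).
#' @param n_pairs Effective number of pairs for reporting (defaults to
#'   `sum(tab)`); used when counts are double-entry weighted.
#' @return A `cor_estimate` with `kind = "tetrachoric"`.
#' @examples
#' tetrachoric_cor(matrix(c(40, 10, 10, 40), 2, 2))  # ~0.809
#' @export
tetrachoric_cor <- function(tab, conf_level = 0.95, n_pairs = NULL) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0))
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("tetrachoric correlation is not identified with a zero margin")
  if (any(tab == 0))
    warning("empty cell: estimate lies at or near the boundary")
  p1 <- sum(tab[2, ]) / n
  p2 <- sum(tab[, 2]) / n
  t1 <- stats::qnorm(1 - p1)
  t2 <- stats::qnorm(1 - p2)
  loglik <- function(r) {
    p11 <- pbvn_upper(t1, t2, r)
    pr <- c(`00` = 1 - stats::pnorm(-t1) - stats::pnorm(-t2) + p11,
            `10` = stats::pnorm(-t1) - p11,
            `01` = stats::pnorm(-t2) - p11,
            `11` = p11)
    sum(c(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2]) *
          log(pmax(pr, 1e-12)))
  }
  opt <- stats::optimize(function(r) -loglik(r), c(-0.9999, 0.9999),
                         tol = 1e-8)
  rhat <- opt$minimum
  prof <- .profile_ci_r(loglik, rhat, conf_level)
  new_cor_estimate(rhat, prof$ci, "tetrachoric", n_pairs %||% n,
                   boundary = prof$boundary || any(tab == 0))
}

#' Polyserial correlation between a binary and a continuous variable
#'
#' Two-step maximum likelihood for the latent bivariate-normal correlation:
#' the continuous margin's mean/SD and the binary threshold are fixed at
#' their sample estimates, then the correlation maximizes the conditional
#' likelihood of the binary outcomes given the continuous values. The CI is
#' profile-likelihood.
#'
#' @param d Binary 0/1 vector.
#' @param y Continuous vector, same length.
#' @param conf_level Confidence level (default 0.95).
#' @param weights Optional non-negative case weights (used for double-entry
#'   pooling).
#' @param n_pairs Effective n for reporting (defaults to the number of
#'   complete cases).
#' @return A `cor_estimate` with `kind = "polyserial"`.
#' @export
polyserial_cor <- function(d, y, conf_level = 0.95, weights = NULL,
                           n_pairs = NULL) {
  keep <- !is.na(d) & !is.na(y)
  d <- d[keep]; y <- y[keep]
  w <- if (is.null(weights)) rep(1, length(d)) else weights[keep]
  if (length(d) < 10) stop("need at least 10 complete observations")
  if (length(unique(d)) < 2) stop("both binary classes must be present")
  if (stats::sd(y) == 0) stop("continuous variable is constant")
  p <- sum(w * d) / sum(w)
  tau <- stats::qnorm(1 - p)
  mu <- sum(w * y) / sum(w)
  sig <- sqrt(sum(w * (y - mu)^2) / sum(w))
  z <- (y - mu) / sig
  s <- 2 * d - 1
  loglik <- function(r) {
    q <- s * (r * z - tau) / sqrt(1 - r^2)
    sum(w * stats::pnorm(q, log.p = TRUE))
  }
  opt <- stats::optimize(function(r) -loglik(r), c(-0.9999, 0.9999),
                         tol = 1e-8)
  rhat <- opt$minimum
  prof <- .profile_ci_r(loglik, rhat, conf_level)
  new_cor_estimate(rhat, prof$ci, "polyserial", n_pairs %||% length(d),
                   boundary = prof$boundary)
}

#' Pearson correlation with a Fisher-z interval
#'
#' Product-moment correlation for two continuous variables; used for the
#' continuous-continuous cells of the stratified correlation table.
#'
#' @param x,y Numeric vectors.
#' @param conf_level Confidence level.
#' @param n_pairs Effective n for the interval (defaults to complete cases);
#'   for double-entered twin data pass the number of pairs.
#' @return A `cor_estimate` with `kind = "pearson"`.
#' @export
pearson_cor <- function(x, y, conf_level = 0.95, n_pairs = NULL) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  r <- stats::cor(x, y)
  n <- n_pairs %||% length(x)
  if (n > 3 && abs(r) < 1) {
    zc <- stats::qnorm(1 - (1 - conf_level) / 2)
    z <- atanh(r)
    ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  new_cor_estimate(r, ci, "pearson", n, boundary = abs(r) >= 1)
}

#' Zygosity- and sex-stratified twin correlations
#'
#' Builds the descriptive correlation table behind the classical twin
#' analysis: per zygosity-sex group, the cross-twin within-trait correlation
#' for the dichotomous trait (tetrachoric, on the double-entered symmetric
#' table), for the continuous trait (Pearson, double-entered), and the
#' cross-twin cross-trait correlation (polyserial, twin 1's binary vs twin
#' 2's continuous pooled with its mirror); plus the within-person
#' (phenotypic) binary-continuous correlation per group and per sex pooled
#' over all individuals. Double-entered estimates count n as pairs, not
#' entries. Groups with fewer than 20 pairs are flagged `low_n` but still
#' estimated; cells whose estimator fails (zero margins and the like) are
#' reported as NA.
#'
#' @param tf A `twin_families` object from [pair_assembly()].
#' @param conf_level Confidence level for all intervals.
#' @return A data.frame with columns `group`, `cell`, `kind`, `r`, `ci_low`,
#'   `ci_high`, `n`, `boundary`, `low_n`.
#' @export
stratified_correlations <- function(tf, conf_level = 0.95) {
  stopifnot(inherits(tf, "twin_families"))
  w <- tf$wide
  rows <- list()
  add <- function(group, cell, est) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, cell = cell, kind = est$kind, r = est$r,
      ci_low = est$ci_low, ci_high = est$ci_high, n = est$n,
      boundary = est$boundary, low_n = est$low_n, stringsAsFactors = FALSE)
  }
  add_na <- function(group, cell, kind, n, msg) {
    rows[[length(rows) + 1]] <<- data.frame(
      group = group, cell = cell, kind = kind, r = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, n = n, boundary = FALSE,
      low_n = n < 20, stringsAsFactors = FALSE)
  }
  try_add <- function(group, cell, kind, n, expr) {
    est <- tryCatch(suppressWarnings(expr), error = function(e) NULL)
    if (is.null(est)) {
      add_na(group, cell, kind, n, NA)
    } else {
      est$low_n <- n < 20
      add(group, cell, est)
    }
  }
  for (g in intersect(c(GROUPS_PAIR), unique(w$group))) {
    wg <- w[w$group == g, ]
    np <- nrow(wg)
    # binary-binary cross-twin: symmetric double-entry, weight 1/2
    cc <- !is.na(wg$d1) & !is.na(wg$d2)
    tab <- 0.5 * (table(factor(wg$d1[cc], 0:1), factor(wg$d2[cc], 0:1)) +
                    table(factor(wg$d2[cc], 0:1), factor(wg$d1[cc], 0:1)))
    try_add(g, "T2DM x T2DM (cross-twin)", "tetrachoric", sum(cc),
            tetrachoric_cor(tab, conf_level, n_pairs = sum(cc)))
    # continuous-continuous cross-twin: double-entered Pearson
    cy <- !is.na(wg$y1) & !is.na(wg$y2)
    try_add(g, "BDI x BDI (cross-twin)", "pearson", sum(cy),
            pearson_cor(c(wg$y1[cy], wg$y2[cy]), c(wg$y2[cy], wg$y1[cy]),
                        conf_level, n_pairs = sum(cy)))
    # cross-trait cross-twin: mirror-pooled polyserial, weight 1/2
    n_ct <- sum(!is.na(wg$d1) & !is.na(wg$y2)) +
      sum(!is.na(wg$d2) & !is.na(wg$y1))
    try_add(g, "T2DM x BDI (cross-twin)", "polyserial", ceiling(n_ct / 2),
            polyserial_cor(c(wg$d1, wg$d2), c(wg$y2, wg$y1), conf_level,
                           weights = rep(0.5, 2 * np),
                           n_pairs = ceiling(n_ct / 2)))
    # within-person phenotypic, both members pooled
    dph <- c(wg$d1, wg$d2); yph <- c(wg$y1, wg$y2)
    nph <- sum(!is.na(dph) & !is.na(yph))
    try_add(g, "T2DM x BDI (within person)", "polyserial", nph,
            polyserial_cor(dph, yph, conf_level))
  }
  # phenotypic correlation pooled by sex over all individuals
  for (s in c("M", "F")) {
    d <- c(w$d1[w$sex1 == s], w$d2[!is.na(w$sex2) & w$sex2 == s])
    y <- c(w$y1[w$sex1 == s], w$y2[!is.na(w$sex2) & w$sex2 == s])
    n <- sum(!is.na(d) & !is.na(y))
    try_add(s, "T2DM x BDI (within person)", "polyserial", n,
            polyserial_cor(d, y, conf_level))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
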