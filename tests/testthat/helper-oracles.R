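# Independent numerical oracles used across the test files. These stay
# deliberately separate from the package's own numerical paths: rectangle
# probabilities come from base-R adaptive quadrature, latent covariances
# from explicit factor-score construction.

# Upper-orthant P(X > h, Y > k) via stats::integrate.
rect_oracle <- function(h, k, rho) {
  if (rho == 0) {
    return(pnorm(h, lower.tail = FALSE) * pnorm(k, lower.tail = FALSE))
  }
  f <- function(x) {
    dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  }
  integrate(f, h, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# General rectangle P(d-coded intervals) for bivariate normal with means m,
# sds s, correlation rho.
rect_oracle_d <- function(tau1, tau2, d1, d2, m1, m2, s1, s2, rho) {
  lo1 <- if (d1 == 1) tau1 else -Inf
  hi1 <- if (d1 == 1) Inf else tau1
  f <- function(x) {
    cm <- m2 + rho * s2 / s1 * (x - m1)
    cs <- s2 * sqrt(1 - rho^2)
    inner <- if (d2 == 1) {
      pnorm((tau2 - cm) / cs, lower.tail = FALSE)
    } else {
      pnorm((tau2 - cm) / cs)
    }
    dnorm(x, m1, s1) * inner
  }
  # piecewise around the density spike so the adaptive rule cannot miss it
  knots <- sort(unique(pmax(pmin(m1 + c(-8, -4, -2, 0, 2, 4, 8) * s1, hi1),
                            lo1)))
  knots <- c(lo1, knots, hi1)
  knots <- knots[!duplicated(knots)]
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    if (knots[i] >= knots[i + 1]) next
    total <- total + integrate(f, knots[i], knots[i + 1],
                               rel.tol = 1e-12, abs.tol = 1e-14,
                               subdivisions = 400L)$value
  }
  total
}

# Family log-likelihood by quadrature: density of observed continuous
# elements times the rectangle probability of observed binary elements,
# with conditional moments obtained through solve() rather than the
# package's Cholesky route.
family_loglik_oracle <- function(family, moments) {
  k <- length(family$d)
  S <- moments$cov
  mu <- moments$mean
  lpos <- seq(1, 2 * k, by = 2)
  ypos <- seq(2, 2 * k, by = 2)
  cont <- ypos[!is.na(family$y)]
  bin <- lpos[!is.na(family$d)]
  ll <- 0
  if (length(cont)) {
    yv <- family$y[!is.na(family$y)]
    Sc <- S[cont, cont, drop = FALSE]
    ll <- ll + as.numeric(
      -0.5 * t(yv - mu[cont]) %*% solve(Sc) %*% (yv - mu[cont]) -
        0.5 * determinant(Sc)$modulus - 0.5 * length(cont) * log(2 * pi))
    B <- S[bin, cont, drop = FALSE] %*% solve(Sc)
    cm <- mu[bin] + as.vector(B %*% (yv - mu[cont]))
    cv <- S[bin, bin, drop = FALSE] - B %*% t(S[bin, cont, drop = FALSE])
  } else {
    cm <- mu[bin]
    cv <- S[bin, bin, drop = FALSE]
  }
  if (length(bin)) {
    mem <- which(!is.na(family$d))
    tau <- moments$thresholds[mem]
    dv <- family$d[mem]
    if (length(bin) == 1) {
      p <- if (dv == 1) {
        pnorm((tau - cm) / sqrt(cv[1, 1]), lower.tail = FALSE)
      } else {
        pnorm((tau - cm) / sqrt(cv[1, 1]))
      }
    } else {
      sds <- sqrt(diag(cv))
      p <- rect_oracle_d(tau[1], tau[2], dv[1], dv[2], cm[1], cm[2],
                         sds[1], sds[2], cv[1, 2] / prod(sds))
    }
    ll <- ll + log(p)
  }
  ll
}

# Latent pair scores built from explicit shared/unique factor construction
# (MZ: identical A; same-sex DZ: A split into a shared half and unique
# halves). Returns n x 4 matrix (l1, y1, l2, y2), zero means.
factor_scores_oracle <- function(paths, group, n) {
  draw2 <- function() matrix(rnorm(2 * n), n, 2)
  A1 <- draw2(); C1 <- draw2()
  if (group %in% c("MZM", "MZF")) {
    A2 <- A1
    C2 <- C1
  } else {
    Ashared <- draw2()
    A1 <- sqrt(0.5) * Ashared + sqrt(0.5) * draw2()
    A2 <- sqrt(0.5) * Ashared + sqrt(0.5) * draw2()
    C2 <- C1
  }
  E1 <- draw2(); E2 <- draw2()
  p1 <- A1 %*% t(paths$a) + C1 %*% t(paths$c) + E1 %*% t(paths$e)
  p2 <- A2 %*% t(paths$a) + C2 %*% t(paths$c) + E2 %*% t(paths$e)
  cbind(p1, p2)[, c(1, 2, 3, 4)]
}

# Small two-group female cohort parameters used by several fitting tests.
female_two_group_params <- function(n_mzf, n_dzf, seed) {
  sim_params(n = c(MZM = 0, MZF = n_mzf, DZM = 0, DZF = n_dzf,
                   DZOS = 0, SGL = 0), seed = seed)
}

# Random valid single-sex path set for property tests.
random_paths <- function() {
  prop <- function() {
    x <- rexp(3) + 0.05
    x / sum(x)
  }
  p1 <- prop(); p2 <- prop()
  cholesky_from_components(
    a2 = c(p1[1], p2[1]), c2 = c(p1[2], p2[2]), e2 = c(p1[3], p2[3]),
    rA = runif(1, -0.9, 0.9), rC = runif(1, -0.9, 0.9),
    rE = runif(1, -0.9, 0.9), var2 = runif(1, 0.5, 2))
}

# Random full parameter set (both sexes) for property tests.
random_ace_params <- function(free_GH = FALSE) {
  p <- sim_params()
  p$paths <- list(M = random_paths(), F = random_paths())
  if (free_GH) {
    p$G <- matrix(runif(4, -0.45, 0.45), 2, 2) + diag(2) * 0.1
    p$H <- matrix(runif(4, -0.45, 0.45), 2, 2) + diag(2) * 0.3
  }
  p$thresholds <- c(M = runif(1, 0.8, 2), F = runif(1, 0.8, 2))
  p$beta_age <- runif(1, -0.05, 0.05)
  p$mu <- c(M = runif(1, -1, 2), F = runif(1, -1, 2))
  p
}
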