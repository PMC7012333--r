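# The FIML likelihood: implied moments, single-family contributions against
# quadrature, and aggregation.

test_that("implied moments respect the constraint maps", {
  p <- sim_params()
  p$paths$M <- p$paths$F  # HomoACE-style equated paths
  mm <- implied_moments(p, "MZM", c(43, 43))
  mf <- implied_moments(p, "MZF", c(43, 43))
  expect_equal(mm$cov, mf$cov, ignore_attr = TRUE)
  # DZOS genetic cross block with G fixed: 0.5 * a_M a_F'
  q <- sim_params()
  S <- expected_pair_covariance(q, "DZOS")
  A_cross <- 0.5 * q$paths$M$a %*% t(q$paths$F$a) +
    q$paths$M$c %*% t(q$paths$F$c)
  expect_equal(unname(S[1:2, 3:4]), A_cross, tolerance = 1e-12)
  # thresholds move with age along the shared slope
  m <- implied_moments(q, "DZF", c(33, 53))
  expect_equal(diff(m$thresholds), q$beta_age * 20)
})

test_that("implied covariances stay positive semi-definite over random draws", {
  set.seed(22)
  for (i in 1:40) {
    p <- random_ace_params(free_GH = i %% 2 == 0)
    for (g in c("MZM", "MZF", "DZM", "DZF", "DZOS")) {
      ev <- eigen(expected_pair_covariance(p, g, check = FALSE),
                  symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8)
    }
  }
})

test_that("continuous-only family reduces to the Gaussian density", {
  mom <- list(mean = rep(0, 4), cov = diag(4), thresholds = c(1, 1))
  fam <- list(d = c(NA, NA), y = c(0, 0))
  expect_equal(family_loglik(fam, mom), 2 * dnorm(0, log = TRUE),
               tolerance = 1e-12)
})

test_that("an infinitely low threshold contributes log(1) for a case", {
  mom <- list(mean = c(0, 0), cov = diag(2), thresholds = -Inf)
  base <- family_loglik(list(d = NA, y = 0.4), mom)
  with_case <- family_loglik(list(d = 1, y = 0.4), mom)
  expect_equal(with_case, base, tolerance = 1e-12)
})

test_that("family likelihood matches the quadrature oracle on random families", {
  set.seed(23)
  worst <- 0
  for (i in 1:100) {
    p <- random_ace_params()
    g <- sample(c("MZM", "MZF", "DZM", "DZF", "DZOS", "SGL"), 1)
    if (g == "SGL") {
      sex <- sample(c("M", "F"), 1)
      mom <- implied_moments(p, g, runif(1, 20, 80), sex = sex)
      fam <- list(d = rbinom(1, 1, 0.5), y = rnorm(1, p$mu[[sex]]))
    } else {
      mom <- implied_moments(p, g, runif(2, 20, 80))
      fam <- list(d = rbinom(2, 1, 0.5), y = rnorm(2))
      # random missingness, keeping at least one observed element
      drop <- sample(0:3, 1)
      if (drop %in% c(1, 3)) fam$d[1 + drop %/% 2] <- NA
      if (drop == 2) fam$y[1] <- NA
    }
    got <- family_loglik(fam, mom)
    want <- family_loglik_oracle(fam, mom)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("the two binary outcomes conserve probability given the same y", {
  set.seed(24)
  for (i in 1:20) {
    p <- random_ace_params()
    mom <- implied_moments(p, "MZF", runif(2, 20, 80))
    yv <- rnorm(2)
    cont <- family_loglik(list(d = c(NA, NA), y = yv), mom)
    lp <- vapply(list(c(1, 1), c(1, 0), c(0, 1), c(0, 0)), function(d) {
      family_loglik(list(d = d, y = yv), mom)
    }, numeric(1))
    expect_equal(sum(exp(lp - cont)), 1, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant under member swap in same-sex pairs", {
  p <- random_ace_params()
  mom <- implied_moments(p, "DZF", c(50, 50))
  fam <- list(d = c(1, 0), y = c(0.4, -1.1))
  swapped <- list(d = rev(fam$d), y = rev(fam$y))
  expect_equal(family_loglik(fam, mom), family_loglik(swapped, mom),
               tolerance = 1e-10)
})

test_that("total -2LL doubles with duplicated data and adds over singletons", {
  p <- sim_params(n = c(MZM = 20, MZF = 20, DZM = 20, DZF = 20, DZOS = 20,
                        SGL = 30), seed = 25)
  coh <- simulate_cohort(p)
  tf <- prepare_cohort(coh)
  m1 <- total_minus2ll(tf, p)
  coh2 <- coh
  coh2$family_id <- paste0(coh2$family_id, "-dup")
  both <- rbind(coh, coh2)
  both <- transform_bdi(both)
  # keep the same residuals as the single copy for exact doubling
  both$y <- rep(transform_bdi(coh)$y, 2)
  m2 <- total_minus2ll(pair_assembly(both), p)
  expect_equal(m2, 2 * m1, tolerance = 1e-8)
  # singleton-only: sum of per-family bivariate contributions
  sg <- transform_bdi(coh[coh$group == "SGL", ][1:25, ])
  tf_s <- pair_assembly(sg)
  per_family <- vapply(seq_len(25), function(i) {
    r <- sg[i, ]
    mom <- implied_moments(p, "SGL", r$age, sex = r$sex)
    family_loglik(list(d = r$t2dm, y = r$y), mom)
  }, numeric(1))
  expect_equal(total_minus2ll(tf_s, p), -2 * sum(per_family),
               tolerance = 1e-8)
})

test_that("-2LL at the generating parameters beats perturbed parameters", {
  p <- sim_params(n = c(MZM = 0, MZF = 400, DZM = 0, DZF = 300, DZOS = 0,
                        SGL = 0), seed = 26)
  tf <- prepare_cohort(simulate_cohort(p))
  truth <- p
  truth$mu <- c(M = 0, F = 0)  # scores are residualized to mean zero
  m_truth <- total_minus2ll(tf, truth)
  worse <- 0
  for (delta in c(-0.2, 0.15, 0.3)) {
    q <- truth
    q$thresholds <- truth$thresholds + delta
    q$mu <- truth$mu + delta
    worse <- worse + (total_minus2ll(tf, q) > m_truth)
  }
  expect_equal(worse, 3)
})
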