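# Synthetic cohort generator: implied covariances and emitted data.

test_that("pair covariance reproduces the univariate sharing algebra", {
  # univariate embedding: trait 2 pure E, trait 1 a=0.6, c=0, e=0.8
  paths <- cholesky_from_components(a2 = c(0.36, 0), c2 = c(0, 0),
                                    e2 = c(0.64, 1))
  p <- sim_params()
  p$paths <- list(M = paths, F = paths)
  S_mz <- expected_pair_covariance(p, "MZF")
  expect_equal(S_mz["l1", "l2"], 0.36, tolerance = 1e-12)
  expect_equal(S_mz["y1", "y2"], 0, tolerance = 1e-12)  # E never shared
  S_dz <- expected_pair_covariance(p, "DZF")
  expect_equal(S_dz["l1", "l2"], 0.18, tolerance = 1e-12)
  expect_equal(S_dz["l1", "l1"], 1, tolerance = 1e-12)
})

test_that("DZOS block reduces to DZ structure under null G and H", {
  p <- sim_params()
  p$paths$M <- p$paths$F  # same paths so only the block rule differs
  expect_equal(expected_pair_covariance(p, "DZOS"),
               expected_pair_covariance(p, "DZF"),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("implied pair covariance matches factor-score simulation", {
  set.seed(21)
  for (g in c("MZF", "DZM")) {
    paths <- random_paths()
    p <- sim_params()
    p$paths <- list(M = paths, F = paths)
    S <- expected_pair_covariance(p, g)
    emp <- cov(factor_scores_oracle(paths, g, 200000))
    expect_equal(unname(S), unname(emp), tolerance = 0.02)
  }
})

test_that("unknown group and invalid parameters are refused", {
  p <- sim_params()
  expect_error(expected_pair_covariance(p, "MZX"), "unknown")
  bad <- p
  bad$paths$F$a[1, 1] <- 0.9  # breaks unit liability variance
  expect_error(expected_pair_covariance(bad, "MZF"), "liability variance")
  bad2 <- p
  bad2$G <- matrix(2, 2, 2)
  expect_error(expected_pair_covariance(bad2, "DZOS"), "\\[-1, 1\\]")
})

test_that("cohort prevalence matches the threshold and extreme thresholds", {
  p <- sim_params(thresholds = c(M = Inf, F = Inf),
                  n = c(MZM = 50, MZF = 50, DZM = 50, DZF = 50,
                        DZOS = 50, SGL = 100))
  expect_equal(sum(simulate_cohort(p)$t2dm), 0)
  # inverse-normal threshold for the reported 471/5975 prevalence, no slope
  prev <- 471 / 5975
  p2 <- sim_params(thresholds = c(M = qnorm(1 - prev), F = qnorm(1 - prev)),
                   beta_age = 0, seed = 5)
  coh <- simulate_cohort(p2)
  phat <- mean(coh$t2dm)
  se <- sqrt(prev * (1 - prev) / nrow(coh))
  expect_lt(abs(phat - prev), 4 * se)
})

test_that("MZ cross-twin tetrachoric recovers a2 + c2 at large n", {
  p <- sim_params(beta_age = 0,
                  n = c(MZM = 0, MZF = 5000, DZM = 0, DZF = 0,
                        DZOS = 0, SGL = 0), seed = 31)
  coh <- simulate_cohort(p)
  w <- pair_assembly(coh)$wide
  tab <- table(factor(w$d1, 0:1), factor(w$d2, 0:1))
  est <- tetrachoric_cor(tab)
  truth <- with(p$paths$F, a[1, 1]^2 + c[1, 1]^2)  # 0.85
  expect_lt(abs(est$r - truth), 0.05)
})

test_that("DZ cross-twin covariance is half the MZ one when C is absent", {
  paths <- cholesky_from_components(a2 = c(0.6, 0.4), c2 = c(0, 0),
                                    e2 = c(0.4, 0.6), rA = 0.5, rE = -0.1)
  p <- sim_params(n = c(MZM = 4000, MZF = 0, DZM = 4000, DZF = 0,
                        DZOS = 0, SGL = 0), seed = 41, beta_age = 0)
  p$paths <- list(M = paths, F = paths)
  coh <- simulate_cohort(p, debug_latents = TRUE)
  cross <- function(g) {
    x <- coh[coh$group == g, ]
    cov(x$latent_score[x$member_index == 1], x$latent_score[x$member_index == 2])
  }
  expect_equal(cross("DZM") / cross("MZM"), 0.5, tolerance = 0.12)
})

test_that("twin labels are exchangeable within same-sex groups", {
  p <- sim_params(n = c(MZM = 0, MZF = 6000, DZM = 0, DZF = 0,
                        DZOS = 0, SGL = 0), seed = 51, beta_age = 0)
  coh <- simulate_cohort(p, debug_latents = TRUE)
  l1 <- coh$liability[coh$member_index == 1]
  l2 <- coh$liability[coh$member_index == 2]
  expect_lt(abs(var(l1) - var(l2)), 0.06)
  expect_lt(abs(mean(l1) - mean(l2)), 0.05)
})

test_that("simulation is deterministic given the seed", {
  p <- sim_params(n = c(MZM = 10, MZF = 10, DZM = 10, DZF = 10,
                        DZOS = 10, SGL = 10), seed = 99)
  expect_identical(simulate_cohort(p), simulate_cohort(p))
  p2 <- p; p2$seed <- 100L
  expect_false(identical(simulate_cohort(p), simulate_cohort(p2)))
})

test_that("integer emission stays on the questionnaire scale", {
  p <- sim_params(n = c(MZM = 50, MZF = 50, DZM = 0, DZF = 0,
                        DZOS = 0, SGL = 50), seed = 61)
  coh <- simulate_cohort(p, bdi = "integer")
  expect_true(all(coh$bdi == round(coh$bdi)))
  expect_true(all(coh$bdi >= 0 & coh$bdi <= 63))
  # skewed: mean well above median for a floor-heavy score
  expect_gt(mean(coh$bdi), median(coh$bdi))
})

test_that("DZOS families are emitted male-first and ages shared", {
  p <- sim_params(n = c(MZM = 0, MZF = 0, DZM = 0, DZF = 0,
                        DZOS = 40, SGL = 0), seed = 71)
  coh <- simulate_cohort(p)
  expect_true(all(coh$sex[coh$member_index == 1] == "M"))
  expect_true(all(coh$sex[coh$member_index == 2] == "F"))
  a <- tapply(coh$age, coh$family_id, function(x) diff(range(x)))
  expect_true(all(unlist(a) == 0))
})

test_that("config round-trips through the flat key-value schema", {
  p <- sim_params(seed = 17)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(p, path)
  q <- read_sim_config(path)
  expect_equal(q$paths, p$paths, tolerance = 1e-12)
  expect_equal(q$n, p$n)
  expect_equal(q$thresholds, p$thresholds)
  a <- simulate_cohort(q)
  b <- simulate_cohort(p)
  expect_identical(a$t2dm, b$t2dm)
  expect_equal(a$bdi, b$bdi, tolerance = 1e-9)
})

test_that("cohort CSV round-trips", {
  p <- sim_params(n = c(MZM = 5, MZF = 5, DZM = 5, DZF = 5, DZOS = 5,
                        SGL = 5), seed = 3)
  coh <- simulate_cohort(p)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$t2dm, coh$t2dm)
  expect_equal(back$bdi, coh$bdi, tolerance = 1e-12)
  expect_error(read_cohort(write_cohort(data.frame(a = 1), tempfile())),
               "missing columns")
})
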