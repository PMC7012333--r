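# Model-ladder bookkeeping, comparisons and small fitting checks.
# Parameter-recovery at the published generating values lives in
# test-acceptance.R; these tests exercise the mechanics on small cohorts.

test_that("free-parameter accounting matches the sex-limitation ladder", {
  expect_equal(count_free_params("HetACEg") - count_free_params("HetACE"), 4)
  expect_equal(count_free_params("HetACEc") - count_free_params("HetACE"), 4)
  expect_equal(count_free_params("HetACE") - count_free_params("HomoACE"), 9)
  expect_equal(count_free_params("HetACE") - count_free_params("HetACE"), 0)
  expect_error(count_free_params("ADE"), "arg")
})

test_that("AIC follows the observed-statistics convention", {
  expect_equal(aic(15429.91, 7799), -168.09)
  expect_equal(aic(15583.57, 7812), -40.43)
  expect_equal(aic(0, 0), 0)
})

test_that("comparisons demand nesting and degenerate to chi2 = 0", {
  f1 <- list(variant = "HetACE", minus2ll = 100, df = 50, aic = 0)
  f2 <- list(variant = "HetACEg", minus2ll = 100, df = 46, aic = 8)
  cmp <- compare_fits(f1, f2)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$delta_df, 4)
  expect_error(compare_fits(f2, f1), "not nested")
  expect_error(compare_fits(f1, f1), "not nested")
})

test_that("selection reproduces the published ladder decision", {
  # printed ladder: qualitative tests non-significant, quantitative highly
  # significant -> quantitative-sex-differences model retained
  cmp <- rbind(
    data.frame(nested = "HetACE", reference = "HetACEg", chi2 = 1.52,
               delta_df = 4, p_value = 0.82, delta_aic = -6.49),
    data.frame(nested = "HetACE", reference = "HetACEc", chi2 = 0.097,
               delta_df = 4, p_value = 0.999, delta_aic = -7.91),
    data.frame(nested = "HomoACE", reference = "HetACE", chi2 = 152.15,
               delta_df = 9, p_value = 1e-27, delta_aic = 134.15))
  sel <- select_best(cmp)
  expect_equal(sel$selected, "HetACE")
  expect_length(sel$trail, 3)
})

test_that("selection retains richer models when constraints are rejected", {
  cmp <- rbind(
    data.frame(nested = "HetACE", reference = "HetACEg", chi2 = 30,
               delta_df = 4, p_value = 1e-5, delta_aic = 22),
    data.frame(nested = "HetACE", reference = "HetACEc", chi2 = 25,
               delta_df = 4, p_value = 1e-4, delta_aic = 17))
  expect_equal(select_best(cmp)$selected, "HetACEg+HetACEc")
  cmp$p_value <- c(1e-5, 0.7)
  cmp$delta_aic <- c(22, -7)
  expect_equal(select_best(cmp)$selected, "HetACEg")
})

test_that("a single supplied model is returned unchanged", {
  f <- structure(list(variant = "HomoACE"), class = "ace_fit")
  expect_equal(select_best(f)$selected, "HomoACE")
})

test_that("the AIC margin rule can overrule a significant test", {
  cmp <- rbind(
    data.frame(nested = "HetACE", reference = "HetACEg", chi2 = 10,
               delta_df = 4, p_value = 0.04, delta_aic = -12),
    data.frame(nested = "HetACE", reference = "HetACEc", chi2 = 1,
               delta_df = 4, p_value = 0.91, delta_aic = -7),
    data.frame(nested = "HomoACE", reference = "HetACE", chi2 = 100,
               delta_df = 9, p_value = 1e-17, delta_aic = 82))
  # p = .04 alone would retain HetACEg, but dAIC favors parsimony by >= 10
  expect_equal(select_best(cmp)$selected, "HetACE")
})

test_that("ladder fits are monotone in -2LL on a mixed-sex cohort", {
  p <- sim_params(n = c(MZM = 90, MZF = 90, DZM = 70, DZF = 70, DZOS = 80,
                        SGL = 60), seed = 33)
  tf <- prepare_cohort(simulate_cohort(p))
  lad <- fit_ladder(tf, restarts = 1, seed = 1)
  m <- vapply(lad$fits, function(f) f$minus2ll, numeric(1))
  tol <- 1e-4
  expect_lte(m["HetACEg"], m["HetACE"] + tol)
  expect_lte(m["HetACEc"], m["HetACE"] + tol)
  expect_lte(m["HetACE"], m["HomoACE"] + tol)
  # df bookkeeping: same data, so df differences equal free-parameter
  # differences from the canonical counts
  expect_equal(lad$fits$HomoACE$df - lad$fits$HetACE$df,
               count_free_params("HetACE") - count_free_params("HomoACE"))
  expect_equal(lad$fits$HetACE$df - lad$fits$HetACEg$df, 4)
  expect_true(all(lad$comparisons$chi2 > -1e-4))
  expect_s3_class(lad$selection, "ace_selection")
  # data were generated under G = 0.5 I; individual G entries are weakly
  # identified at this size, but the qualitative likelihood-ratio test
  # should not be extreme under its own null
  chi_g <- lad$comparisons[lad$comparisons$reference == "HetACEg", "chi2"]
  expect_lt(chi_g, qchisq(0.999, 4))
})

test_that("fitting refuses empty data and unknown variants", {
  p <- sim_params(n = c(MZM = 15, MZF = 15, DZM = 0, DZF = 0, DZOS = 0,
                        SGL = 0), seed = 34)
  tf <- prepare_cohort(simulate_cohort(p))
  expect_error(fit_ace(tf, "ACE-plus"), "arg")
  expect_warning(
    fit_ace(pair_assembly(transform_bdi(
      simulate_cohort(sim_params(n = c(MZM = 40, MZF = 0, DZM = 0, DZF = 0,
                                       DZOS = 0, SGL = 0), seed = 35)))),
      "HetACE", restarts = 1, control = list(maxit = 5)),
    "fewer than 2 zygosity groups")
})

test_that("freeing G without opposite-sex pairs degrades gracefully", {
  p <- sim_params(n = c(MZM = 40, MZF = 40, DZM = 30, DZF = 30, DZOS = 0,
                        SGL = 0), seed = 36)
  tf <- prepare_cohort(simulate_cohort(p))
  expect_warning(f <- fit_ace(tf, "HetACEg", restarts = 1,
                              control = list(maxit = 20)),
                 "not\\s+identified")
  expect_false("g11" %in% f$layout$name)
})
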