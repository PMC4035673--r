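test_that("Begg naive variant: exact p on monotone k=3 examples", {
  b <- begg_test(effects_df(c(1, 2, 3), c(3, 2, 1)), variant = "naive")
  expect_equal(b$slope_or_tau, -1)
  expect_equal(b$p_value, 1 / 3)
  b <- begg_test(effects_df(c(1, 2, 3), c(1, 2, 3)), variant = "naive")
  expect_equal(b$slope_or_tau, 1)
  expect_equal(b$p_value, 1 / 3)
})

test_that("Begg exact p equals brute-force permutation enumeration", {
  set.seed(101)
  for (k in c(5, 6, 8)) {
    e <- random_effects(k)
    b <- begg_test(e, variant = "naive")
    # oracle enumerates rank permutations of the naive variables
    expect_equal(b$p_value, brute_kendall_p(e$ln_dor, e$var_ln_dor),
                 tolerance = 1e-12)
    # standardized variant against the same oracle on the deviates
    bs <- begg_test(e, variant = "standardized")
    w <- 1 / e$var_ln_dor
    dev <- (e$ln_dor - sum(w * e$ln_dor) / sum(w)) /
      sqrt(e$var_ln_dor - 1 / sum(w))
    expect_equal(bs$p_value, brute_kendall_p(dev, e$var_ln_dor),
                 tolerance = 1e-12)
  }
})

test_that("Begg exact and continuity-corrected normal p agree within 0.02 at k >= 8", {
  set.seed(55)
  for (i in 1:10) {
    e <- random_effects(8)
    exact <- begg_test(e, variant = "naive", exact_max_k = 8)
    approx <- begg_test(e, variant = "naive", exact_max_k = 0,
                        z_continuity = TRUE)
    expect_lt(abs(exact$p_value - approx$p_value), 0.02)
    # the default (uncorrected) z is close in the tails that matter
    plain <- begg_test(e, variant = "naive", exact_max_k = 0)
    if (exact$p_value < 0.1) {
      expect_lt(abs(exact$p_value - plain$p_value), 0.02)
    }
  }
})

test_that("Begg guards: small k, tied ranks", {
  expect_error(begg_test(effects_df(c(1, 2), c(1, 2))), "insufficient data")
  b <- begg_test(effects_df(c(1, 1, 1), c(2, 2, 2)), variant = "naive")
  expect_equal(b$p_value, 1)
  expect_match(b$notes, "degenerate")
  expect_false(b$significant)
})

test_that("Egger matches the WLS normal-equations oracle", {
  e <- effects_df(c(1.0, 1.2, 0.8, 1.0), c(0.5, 0.4, 0.3, 0.2)^2)
  g <- egger_test(e)
  o <- wls_oracle(e$se_ln_dor, e$ln_dor, 1 / e$var_ln_dor)
  expect_equal(g$slope_or_tau, o$slope, tolerance = 1e-10)
  expect_equal(g$statistic, o$t, tolerance = 1e-10)
  expect_equal(g$p_value, o$p, tolerance = 1e-10)
  expect_equal(g$df, 2L)
})

test_that("Egger weighted form equals the classical intercept form", {
  set.seed(77)
  for (i in 1:25) {
    e <- random_effects(sample(4:20, 1))
    g <- egger_test(e)
    # classical: standardized effect on precision, unweighted, intercept test
    fit <- summary(lm(I(e$ln_dor / e$se_ln_dor) ~ I(1 / e$se_ln_dor)))
    expect_equal(g$slope_or_tau, unname(fit$coefficients[1, 1]),
                 tolerance = 1e-10)
    expect_equal(abs(g$statistic), abs(unname(fit$coefficients[1, 3])),
                 tolerance = 1e-10)
    expect_equal(g$p_value, unname(fit$coefficients[1, 4]), tolerance = 1e-10)
  }
})

test_that("Egger degeneracies are flagged, not fatal", {
  # exact linear fit: ln_dor = 2 * se
  se <- c(0.2, 0.3, 0.4, 0.5)
  g <- egger_test(effects_df(2 * se, se^2))
  expect_equal(g$slope_or_tau, 2, tolerance = 1e-10)
  expect_true(is.na(g$p_value))
  expect_match(g$notes, "zero residual variance")
  # identical SEs: constant regressor
  g2 <- egger_test(effects_df(c(1, 2, 3, 2), rep(0.25, 4)))
  expect_match(g2$notes, "constant regressor")
  expect_error(egger_test(effects_df(c(1, 2), c(1, 2))), "insufficient data")
})

test_that("Deeks matches the WLS oracle and is scale-equivariant in ESS", {
  set.seed(88)
  e <- random_effects(5)
  d <- deeks_test(e)
  o <- wls_oracle(e$inv_sqrt_ess, e$ln_dor, e$ess)
  expect_equal(d$slope_or_tau, o$slope, tolerance = 1e-10)
  expect_equal(d$statistic, o$t, tolerance = 1e-10)
  expect_equal(d$p_value, o$p, tolerance = 1e-10)

  # scaling all ESS by 4 halves the regressor, doubles the slope, keeps t/p
  e4 <- effects_df(e$ln_dor, e$var_ln_dor, ess = 4 * e$ess)
  d4 <- deeks_test(e4)
  expect_equal(d4$slope_or_tau, 2 * d$slope_or_tau, tolerance = 1e-10)
  expect_equal(d4$statistic, d$statistic, tolerance = 1e-10)
  expect_equal(d4$p_value, d$p_value, tolerance = 1e-10)

  # flat funnel: constant ln_dor, varying ESS
  flat <- deeks_test(effects_df(rep(1.5, 5), runif(5, 0.2, 1),
                                ess = c(20, 50, 90, 140, 200)))
  expect_match(flat$notes, "degenerate")
})

test_that("all three tests are invariant to study order", {
  set.seed(99)
  e <- random_effects(9)
  perm <- sample(9)
  ep <- e[perm, ]
  class(ep) <- class(e)
  for (f in list(function(x) begg_test(x), egger_test, deeks_test)) {
    a <- f(e); b <- f(ep)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  }
})

test_that("run_all_tests captures guards without aborting", {
  m2 <- meta_analysis("tiny", data.frame(study_id = c("a", "b"),
                                         tp = c(5, 6), fp = c(2, 3),
                                         fn = c(3, 2), tn = c(7, 8)))
  res <- run_all_tests(m2, run_config())
  expect_named(res, c("begg", "egger", "deeks"))
  for (r in res) {
    expect_true(is.na(r$p_value))
    expect_match(paste(r$notes, collapse = " "), "insufficient-data")
  }

  set.seed(4)
  corp <- random_corpus(1, k = 12)
  res <- run_all_tests(corp$metas[[1]], run_config())
  for (r in res) {
    expect_gte(r$p_value, 0)
    expect_lte(r$p_value, 1)
    expect_identical(r$significant, r$p_value < 0.05)
  }

  # below the reporting threshold: low-power note
  corp5 <- random_corpus(1, k = 5)
  res5 <- run_all_tests(corp5$metas[[1]], run_config(min_k_warn = 10))
  for (r in res5) {
    if (is.finite(r$p_value)) {
      expect_match(paste(r$notes, collapse = " "), "low-power")
    }
  }
})
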