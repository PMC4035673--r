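test_that("seed determinism: identical scenario gives bit-identical corpora", {
  sc <- simulation_scenario(n_metas = 6, ln_dor_true = 1.5, tau = 0.4,
                            sigma_theta = 0.5, seed = 99)
  a <- simulate_corpus(sc)
  b <- simulate_corpus(sc)
  expect_identical(corpus_to_df(a$corpus), corpus_to_df(b$corpus))
  expect_identical(a$truth, b$truth)
  expect_equal(length(a$corpus$metas), 6)
})

test_that("study construction: ROC identity and central operating points", {
  # logit(sens) - logit(1 - spec) = Lambda_i exactly, for every study
  sc <- simulation_scenario(n_metas = 1, ln_dor_true = 2, tau = 0.8,
                            sigma_theta = 0.9, k = 30, seed = 7)
  set.seed(sc$seed)
  for (i in 1:30) {
    tab <- simulate_study(sc)
    s <- attr(tab, "sens"); sp <- attr(tab, "spec")
    expect_equal(qlogis(s) - qlogis(1 - sp), attr(tab, "ln_dor_i"),
                 tolerance = 1e-12)
  }
  # no-variation scenarios pin the operating point
  sc0 <- simulation_scenario(n_metas = 1, ln_dor_true = 0, k = 5, seed = 1)
  set.seed(1)
  tab <- simulate_study(sc0)
  expect_equal(attr(tab, "sens"), 0.5)
  expect_equal(attr(tab, "spec"), 0.5)
  sc81 <- simulation_scenario(n_metas = 1, ln_dor_true = log(81), k = 5, seed = 1)
  set.seed(1)
  tab81 <- simulate_study(sc81)
  expect_equal(attr(tab81, "sens"), 0.9, tolerance = 1e-12)
  expect_equal(attr(tab81, "spec"), 0.9, tolerance = 1e-12)
})

test_that("k-distribution calibration: median ~13, IQR ~(9, 19)", {
  sc <- simulation_scenario(seed = 123)
  set.seed(123)
  ks <- replicate(10000, dtabias:::.draw_trunc(sc$k_distribution))
  expect_true(all(ks >= 4 & ks <= 118))
  expect_gte(median(ks), 11); expect_lte(median(ks), 15)
  q <- quantile(ks, c(0.25, 0.75))
  expect_lte(abs(q[[1]] - 9), 2)
  expect_lte(abs(q[[2]] - 19), 2)
})

test_that("selection rule: step behaviour and no-op limits", {
  strong <- study_table("s", 95, 5, 5, 95)     # overwhelming accuracy
  weak <- study_table("w", 26, 25, 25, 26)     # DOR ~ 1
  none <- selection_rule("none")
  expect_true(apply_selection(weak, none))
  expect_true(apply_selection(strong, selection_rule("p_step", retain_prob = 0)))
  expect_false(apply_selection(weak, selection_rule("p_step", retain_prob = 0)))
  expect_true(apply_selection(weak, selection_rule("p_step", retain_prob = 1)))
  expect_error(selection_rule("p_step", retain_prob = 1.2), "\\[0, 1\\]")

  # retain_prob = 1 is stream-identical to no selection
  sc_none <- simulation_scenario(n_metas = 4, ln_dor_true = 1, seed = 5,
                                 suppression = selection_rule("none"))
  sc_keep <- simulation_scenario(n_metas = 4, ln_dor_true = 1, seed = 5,
                                 suppression = selection_rule("p_step",
                                                              retain_prob = 1))
  expect_identical(corpus_to_df(simulate_corpus(sc_none)$corpus),
                   corpus_to_df(simulate_corpus(sc_keep)$corpus))
})

test_that("unbiased scenario: pooled lnDOR is consistent with the truth", {
  lambda <- 1.2
  sc <- simulation_scenario(n_metas = 200, ln_dor_true = lambda, k = 8,
                            seed = 202)
  sim <- simulate_corpus(sc)
  mus <- vapply(sim$corpus$metas, function(m)
    pool_ln_dor(meta_effects(m), "fixed")$ln_dor_pooled, numeric(1))
  mc_se <- sd(mus) / sqrt(length(mus))
  # small-sample log-OR bias is O(1/n), so allow 3 MC-SE around the truth
  expect_lt(abs(mean(mus) - lambda), 3 * mc_se + 0.05)
})

test_that("suppression shifts published effects upward", {
  sc_no <- simulation_scenario(n_metas = 50, ln_dor_true = log(2), k = 10,
                               seed = 77)
  sc_yes <- simulation_scenario(n_metas = 50, ln_dor_true = log(2), k = 10,
                                suppression = selection_rule("p_step",
                                                             retain_prob = 0.1),
                                seed = 77)
  m_no <- mean(unlist(lapply(simulate_corpus(sc_no)$corpus$metas,
                             function(m) meta_effects(m)$ln_dor)))
  m_yes <- mean(unlist(lapply(simulate_corpus(sc_yes)$corpus$metas,
                              function(m) meta_effects(m)$ln_dor)))
  expect_gt(m_yes, m_no)
})

test_that("operating-characteristics table is well formed", {
  oc <- estimate_operating_characteristics(
    simulation_scenario(ln_dor_true = 0, k = 10, seed = 3),
    n_replicates = 100, tests = c("deeks"))
  expect_equal(oc$test, "deeks")
  expect_equal(oc$n_ok + oc$n_error, 100)
  expect_true(oc$ci_lo <= oc$rate && oc$rate <= oc$ci_hi)
  expect_error(estimate_operating_characteristics(
    simulation_scenario(seed = 1), n_replicates = 50), ">= 100")
})
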