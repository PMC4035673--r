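# quick fixture: one bias_test_result with a given p-value
res_fix <- function(meta, test, p, alpha = 0.05) {
  dtabias:::.new_bias_result(meta, test, 0, 0, p, alpha, k = 10)
}

test_that("call matrix applies a strict p < alpha rule and tracks exclusions", {
  res <- c(lapply(1:3, function(i) res_fix(paste0("m", i), "begg", 0.01)),
           lapply(1:3, function(i) res_fix(paste0("m", i), "deeks", 0.01)))
  cm <- build_call_matrix(res, alpha = 0.05)
  expect_true(all(cm$sig))

  # p exactly at alpha is NOT significant
  cm2 <- build_call_matrix(list(res_fix("m1", "begg", 0.05),
                                res_fix("m1", "deeks", 0.049999)),
                           alpha = 0.05)
  expect_false(cm2$sig["m1", "begg"])
  expect_true(cm2$sig["m1", "deeks"])

  # failed test propagates as exclusion with its reason
  bad <- dtabias:::.new_bias_result("m9", "egger", NA, NA, NA, 0.05, 2,
                                    notes = "insufficient-data")
  cm3 <- build_call_matrix(c(res, list(bad)), alpha = 0.05)
  expect_true(is.na(cm3$sig["m9", "egger"]))
  expect_equal(cm3$excluded$reason, "insufficient-data")

  expect_error(build_call_matrix(c(res, res[1])), "integrity error")
})

test_that("kappa: hand-computed values, perfect agreement, bounds", {
  # both=10, a-only=10, b-only=10, neither=70 -> po .8, pe .68, kappa .375
  res <- list()
  for (i in 1:100) {
    a_sig <- i <= 20          # rows 1-10 both, 11-20 a-only
    b_sig <- i <= 10 || (i > 20 & i <= 30)
    res <- c(res, list(res_fix(sprintf("m%03d", i), "begg",
                               ifelse(a_sig, 0.01, 0.5)),
                       res_fix(sprintf("m%03d", i), "egger",
                               ifelse(b_sig, 0.01, 0.5))))
  }
  cm <- build_call_matrix(res, 0.05)
  cc <- pairwise_concordance(cm, "begg", "egger")
  expect_equal(unname(cc$agreement_table["a_sig", "b_sig"]), 10)
  expect_equal(unname(cc$agreement_table["a_notsig", "b_notsig"]), 70)
  expect_equal(cc$concordance_pct, 80)
  expect_equal(cc$kappa, 0.375)
  expect_equal(cc$n, 100)
  expect_true(cc$kappa_ci[1] < cc$kappa, cc$kappa < cc$kappa_ci[2])

  # perfect agreement
  res2 <- unlist(lapply(1:10, function(i) {
    p <- ifelse(i <= 4, 0.01, 0.5)
    list(res_fix(paste0("m", i), "begg", p), res_fix(paste0("m", i), "deeks", p))
  }), recursive = FALSE)
  cc2 <- pairwise_concordance(build_call_matrix(res2, 0.05), "begg", "deeks")
  expect_equal(cc2$kappa, 1)
  expect_equal(cc2$concordance_pct, 100)
})

test_that("concordance is symmetric up to transposition of the table", {
  set.seed(17)
  res <- unlist(lapply(1:30, function(i) {
    list(res_fix(paste0("m", i), "begg", runif(1)),
         res_fix(paste0("m", i), "deeks", runif(1)))
  }), recursive = FALSE)
  cm <- build_call_matrix(res, 0.2)
  ab <- pairwise_concordance(cm, "begg", "deeks")
  ba <- pairwise_concordance(cm, "deeks", "begg")
  expect_equal(ab$kappa, ba$kappa)
  expect_equal(ab$concordance_pct, ba$concordance_pct)
  expect_equal(ab$agreement_table[1, 2], ba$agreement_table[2, 1])
})

test_that("independent calls give kappa near zero", {
  set.seed(19)
  n <- 4000
  res <- unlist(lapply(seq_len(n), function(i) {
    list(res_fix(sprintf("m%05d", i), "begg", runif(1)),
         res_fix(sprintf("m%05d", i), "egger", runif(1)))
  }), recursive = FALSE)
  cc <- pairwise_concordance(build_call_matrix(res, 0.3), "begg", "egger")
  # MC error on kappa is about 1/sqrt(n * p(1-p)); 4 SE band
  expect_lt(abs(cc$kappa), 4 / sqrt(n * 0.3 * 0.7))
})

test_that("bootstrap CI brackets kappa and leaves the RNG stream alone", {
  set.seed(29)
  res <- unlist(lapply(1:40, function(i) {
    list(res_fix(paste0("m", i), "begg", runif(1)),
         res_fix(paste0("m", i), "egger", runif(1)))
  }), recursive = FALSE)
  cm <- build_call_matrix(res, 0.3)
  state <- .Random.seed
  cc <- pairwise_concordance(cm, "begg", "egger", ci = "bootstrap",
                             n_boot = 500, boot_seed = 7)
  expect_identical(state, .Random.seed)
  expect_lte(cc$kappa_ci[1], cc$kappa)
  expect_gte(cc$kappa_ci[2], cc$kappa)
  cc2 <- pairwise_concordance(cm, "begg", "egger", ci = "bootstrap",
                              n_boot = 500, boot_seed = 7)
  expect_identical(cc$kappa_ci, cc2$kappa_ci)
})

test_that("degenerate and insufficient cases are flagged", {
  res <- unlist(lapply(1:5, function(i) {
    list(res_fix(paste0("m", i), "begg", 0.5),
         res_fix(paste0("m", i), "egger", 0.5))
  }), recursive = FALSE)
  cc <- pairwise_concordance(build_call_matrix(res, 0.05), "begg", "egger")
  expect_true(is.na(cc$kappa))
  expect_match(cc$notes, "undefined")

  one <- list(res_fix("m1", "begg", 0.5), res_fix("m1", "egger", 0.5))
  expect_error(pairwise_concordance(build_call_matrix(one, 0.05),
                                    "begg", "egger"), "insufficient data")
})

test_that("p-value scatter renders with annotation", {
  set.seed(23)
  res <- unlist(lapply(1:20, function(i) {
    list(res_fix(paste0("m", i), "begg", runif(1)),
         res_fix(paste0("m", i), "deeks", runif(1)))
  }), recursive = FALSE)
  cm <- build_call_matrix(res, 0.05)
  path <- withr::local_tempfile(fileext = ".png")
  out <- pvalue_scatter(cm, "deeks", "begg", path)
  expect_gt(file.size(path), 0)
  cc <- pairwise_concordance(cm, "deeks", "begg")
  expect_match(attr(out, "annotation"), sprintf("%.3f", cc$kappa),
               fixed = TRUE)

  # single shared meta still renders
  one <- list(res_fix("m1", "begg", 0.4), res_fix("m1", "deeks", 0.6))
  path2 <- withr::local_tempfile(fileext = ".png")
  pvalue_scatter(build_call_matrix(one, 0.05), "deeks", "begg", path2)
  expect_gt(file.size(path2), 0)
})
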