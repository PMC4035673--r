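# Funnel-asymmetry tests for diagnostic accuracy meta-analyses.
#
# All three tests operate on per-study log diagnostic odds ratios. Their
# null hypothesis is "no small study-effects": no association between the
# effect estimate and the study's precision/size.

# ---- Kendall machinery (Begg) ------------------------------------------

# Kendall S statistic and tie bookkeeping between two numeric vectors.
.kendall_s <- function(x, y) {
  k <- length(x)
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  S <- sum(sx[up] * sy[up])
  tie_x <- table(x); tie_x <- tie_x[tie_x > 1]
  tie_y <- table(y); tie_y <- tie_y[tie_y > 1]
  n0 <- k * (k - 1) / 2
  n1 <- sum(tie_x * (tie_x - 1) / 2)
  n2 <- sum(tie_y * (tie_y - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  list(S = S, tau = if (denom > 0) S / denom else NA_real_,
       k = k, tie_x = as.numeric(tie_x), tie_y = as.numeric(tie_y),
       any_tie = length(tie_x) + length(tie_y) > 0,
       all_tied = n0 == n1 || n0 == n2)
}

# Null distribution of Kendall S for tie-free samples of size k.
# The number of discordant pairs is the permutation inversion number, whose
# distribution has generating function prod_{i=1..k} (1 + q + ... + q^(i-1));
# S = k(k-1)/2 - 2 * inversions. Returns P(S = s) over s = -n0, ..., n0.
.kendall_s_null <- function(k) {
  counts <- 1
  for (i in seq_len(k)) {
    # convolve with the uniform polynomial 1 + q + ... + q^(i-1)
    new <- numeric(length(counts) + i - 1)
    for (m in 0:(i - 1)) {
      idx <- seq_along(counts) + m
      new[idx] <- new[idx] + counts
    }
    counts <- new
  }
  n0 <- k * (k - 1) / 2
  list(s = n0 - 2 * (seq_along(counts) - 1), prob = counts / sum(counts))
}

# Two-sided exact p-value for observed S under the tie-free null.
.kendall_exact_p <- function(S, k) {
  d <- .kendall_s_null(k)
  lo <- sum(d$prob[d$s <= S])
  hi <- sum(d$prob[d$s >= S])
  min(1, 2 * min(lo, hi))
}

# Tie-corrected variance of S (as used by the standard normal approximation).
.kendall_var_s <- function(k, tie_x, tie_y) {
  t <- tie_x; u <- tie_y
  v0 <- k * (k - 1) * (2 * k + 5)
  vt <- sum(t * (t - 1) * (2 * t + 5))
  vu <- sum(u * (u - 1) * (2 * u + 5))
  v1 <- sum(t * (t - 1) * (t - 2)) * sum(u * (u - 1) * (u - 2)) /
    (9 * k * (k - 1) * (k - 2))
  v2 <- sum(t * (t - 1)) * sum(u * (u - 1)) / (2 * k * (k - 1))
  (v0 - vt - vu) / 18 + v1 + v2
}

.new_bias_result <- function(meta_id, test, statistic, slope_or_tau, p_value,
                             alpha, k, df = NA_integer_, notes = character()) {
  structure(list(meta_id = meta_id, test = test,
                 statistic = statistic, slope_or_tau = slope_or_tau,
                 p_value = p_value,
                 significant = isTRUE(is.finite(p_value) && p_value < alpha),
                 alpha = alpha, k = k, df = df, notes = notes),
            class = "bias_test_result")
}

#' @export
print.bias_test_result <- function(x, ...) {
  cat("<", x$test, " test> meta ", x$meta_id, ": stat = ",
      signif(x$statistic, 4), ", p = ", signif(x$p_value, 4),
      if (x$significant) " *" else "", " (k = ", x$k, ")\n", sep = "")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
as.data.frame.bias_test_result <- function(x, ...) {
  data.frame(meta_id = x$meta_id, test = x$test,
             statistic = x$statistic, slope_or_tau = x$slope_or_tau,
             p_value = x$p_value, significant = x$significant,
             k = x$k, df = as.integer(x$df),
             notes = paste(x$notes, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Begg's rank-correlation test for small study-effects
#'
#' Tests for association between per-study effect estimates and their
#' variances via Kendall's tau-b. In the `"standardized"` variant (the
#' original formulation, default) effects are first centred on the
#' inverse-variance-weighted pooled mean and standardized by the variance of
#' the deviation, removing the spurious correlation induced by the pooled
#' estimate; the `"naive"` variant correlates the raw log DOR with its
#' variance.
#'
#' @param effects A `study_effects` data.frame (see [meta_effects()]),
#'   k >= 3 studies.
#' @param variant `"standardized"` (default) or `"naive"`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param exact_max_k Exact enumeration of the tau null distribution is used
#'   for tie-free data up to this many studies (default 8); beyond that, or
#'   with ties, the tie-corrected normal approximation of S is used.
#' @param z_continuity Apply the lattice continuity correction `|S| - 1` in
#'   the normal approximation. Off by default; switching it on brings the
#'   approximate p within ~0.01 of the exact p already at k = 8.
#' @param meta_id Label carried into the result.
#' @return A `bias_test_result`: `statistic` is the normal deviate `z` (or
#'   the exact-path S), `slope_or_tau` is Kendall's tau-b.
#' @references Begg CB, Mazumdar M (1994) Biometrics 50:1088-1101.
#' @export
begg_test <- function(effects, variant = c("standardized", "naive"),
                      alpha = 0.05, exact_max_k = 8, z_continuity = FALSE,
                      meta_id = attr(effects, "meta_id") %||% "") {
  variant <- match.arg(variant)
  y <- effects$ln_dor
  v <- effects$var_ln_dor
  k <- length(y)
  if (k < 3) stop("insufficient data: Begg's test needs >= 3 studies", call. = FALSE)
  if (variant == "standardized") {
    w <- 1 / v
    ybar <- sum(w * y) / sum(w)
    vdev <- v - 1 / sum(w)  # variance of y_i - ybar; > 0 for k >= 2
    x_eff <- (y - ybar) / sqrt(vdev)
  } else {
    x_eff <- y
  }
  ks <- .kendall_s(x_eff, v)
  notes <- character()
  if (ks$all_tied) {
    return(.new_bias_result(meta_id, "begg", NA_real_, NA_real_, 1,
                            alpha, k, notes = "degenerate: all ranks tied"))
  }
  if (!ks$any_tie && k <= exact_max_k) {
    p <- .kendall_exact_p(ks$S, k)
    stat <- ks$S
    notes <- c(notes, "exact")
  } else {
    vs <- .kendall_var_s(k, ks$tie_x, ks$tie_y)
    num <- if (z_continuity) sign(ks$S) * max(0, abs(ks$S) - 1) else ks$S
    stat <- num / sqrt(vs)
    p <- 2 * pnorm(-abs(stat))
    if (ks$any_tie) notes <- c(notes, "ties: normal approximation")
  }
  .new_bias_result(meta_id, "begg", stat, ks$tau, p, alpha, k, notes = notes)
}

# ---- Weighted least squares core (Egger, Deeks) ------------------------

# Simple-regression WLS of y on x with weights w; t-test of the slope on
# k - 2 df. Returns slope, its SE, t, p, plus degeneracy flags.
.wls_slope_test <- function(x, y, w, rel_tol = 1e-10) {
  k <- length(y)
  sw <- sum(w)
  xbar <- sum(w * x) / sw
  ybar <- sum(w * y) / sw
  sxx <- sum(w * (x - xbar)^2)
  if (sxx <= rel_tol * sw * max(xbar^2, 1)) {
    return(list(slope = NA_real_, se = NA_real_, t = NA_real_, p = NA_real_,
                df = k - 2L, degenerate = "constant regressor"))
  }
  slope <- sum(w * (x - xbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- y - intercept - slope * x
  rss <- sum(w * resid^2)
  tss <- sum(w * (y - ybar)^2)
  if (rss <= rel_tol * max(tss, 1)) {
    return(list(slope = slope, se = 0, t = NA_real_, p = NA_real_,
                df = k - 2L, degenerate = "zero residual variance"))
  }
  s2 <- rss / (k - 2)
  se <- sqrt(s2 / sxx)
  tval <- slope / se
  list(slope = slope, se = se, t = tval, p = 2 * pt(-abs(tval), df = k - 2),
       df = k - 2L, degenerate = NULL)
}

#' Egger's regression test for small study-effects
#'
#' Weighted least squares of the log DOR on its standard error, weighted by
#' the inverse variance; the slope is tested against zero with a Student-t
#' on k - 2 degrees of freedom. This is algebraically identical to the
#' classical formulation (unweighted regression of the standardized effect
#' `lnDOR/SE` on precision `1/SE`, testing the intercept): dividing the
#' weighted model through by SE maps the SE slope onto the classical
#' intercept, with identical residuals.
#'
#' @inheritParams begg_test
#' @return A `bias_test_result`: `statistic` is t, `slope_or_tau` the SE
#'   slope (the classical "bias" intercept).
#' @references Egger M et al. (1997) BMJ 315:629-634.
#' @export
egger_test <- function(effects, alpha = 0.05,
                       meta_id = attr(effects, "meta_id") %||% "") {
  y <- effects$ln_dor
  se <- effects$se_ln_dor
  k <- length(y)
  if (k < 3) stop("insufficient data: Egger's test needs >= 3 studies", call. = FALSE)
  fit <- .wls_slope_test(se, y, 1 / effects$var_ln_dor)
  notes <- if (is.null(fit$degenerate)) character() else
    paste0("degenerate: ", fit$degenerate)
  .new_bias_result(meta_id, "egger", fit$t, fit$slope, fit$p,
                   alpha, k, df = fit$df, notes = notes)
}

#' Deeks' effective-sample-size regression test
#'
#' The funnel-asymmetry test developed for diagnostic accuracy
#' meta-analyses: weighted least squares of the log DOR on
#' `1/sqrt(ESS)`, weighted by the effective sample size, testing the slope
#' on k - 2 degrees of freedom. Using the ESS rather than a variance-based
#' precision breaks the intrinsic correlation between the DOR and its
#' standard error that inflates the type-I error of Begg's and Egger's
#' tests on accuracy data.
#'
#' @inheritParams begg_test
#' @return A `bias_test_result`: `statistic` is t, `slope_or_tau` the slope.
#' @references Deeks JJ, Macaskill P, Irwig L (2005) J Clin Epidemiol
#'   58:882-893.
#' @export
deeks_test <- function(effects, alpha = 0.05,
                       meta_id = attr(effects, "meta_id") %||% "") {
  y <- effects$ln_dor
  k <- length(y)
  if (k < 3) stop("insufficient data: Deeks' test needs >= 3 studies", call. = FALSE)
  fit <- .wls_slope_test(effects$inv_sqrt_ess, y, effects$ess)
  notes <- if (is.null(fit$degenerate)) character() else
    paste0("degenerate: ", fit$degenerate)
  .new_bias_result(meta_id, "deeks", fit$t, fit$slope, fit$p,
                   alpha, k, df = fit$df, notes = notes)
}

#' Run all enabled asymmetry tests on one meta-analysis
#'
#' Per-test failures (e.g. too few studies) are captured as flagged results
#' with `p_value = NA`, never aborting a corpus run. Results for
#' meta-analyses smaller than `config$min_k_warn` carry a low-power note.
#'
#' @param meta A [meta_analysis()].
#' @param config A [run_config()]; controls alpha, the Begg variant,
#'   continuity correction and enabled tests.
#' @return Named list of `bias_test_result`, one per enabled test.
#' @export
run_all_tests <- function(meta, config = run_config()) {
  eff <- tryCatch(meta_effects(meta, continuity = config$continuity),
                  error = function(e) e)
  out <- list()
  for (test in config$tests) {
    res <- if (inherits(eff, "error")) {
      .new_bias_result(meta$meta_id, test, NA_real_, NA_real_, NA_real_,
                       config$alpha, nrow(meta$studies),
                       notes = paste0("effects error: ", conditionMessage(eff)))
    } else {
      tryCatch(
        switch(test,
               begg = begg_test(eff, variant = config$begg_variant,
                                alpha = config$alpha, meta_id = meta$meta_id),
               egger = egger_test(eff, alpha = config$alpha,
                                  meta_id = meta$meta_id),
               deeks = deeks_test(eff, alpha = config$alpha,
                                  meta_id = meta$meta_id)),
        error = function(e) {
          .new_bias_result(meta$meta_id, test, NA_real_, NA_real_, NA_real_,
                           config$alpha, nrow(meta$studies),
                           notes = if (grepl("insufficient data", conditionMessage(e)))
                             "insufficient-data" else conditionMessage(e))
        })
    }
    if (is.finite(res$p_value) && res$k < config$min_k_warn) {
      res$notes <- c(res$notes, "low-power: k below reporting threshold")
    }
    out[[test]] <- res
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
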