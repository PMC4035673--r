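# Simulator of diagnostic test accuracy meta-analysis corpora with known
# truth: the stand-in for literature corpora whose 2x2 tables are rarely
# deposited. Supports null scenarios, between-study heterogeneity in the
# DOR, threshold (positivity cut-off) variation, and an explicit
# selective-publication mechanism.

#' Describe a selective-publication mechanism
#'
#' @param mode `"none"` (every study published) or `"p_step"`: a study is
#'   always published if its one-sided Wald p-value for `lnDOR > 0` is
#'   below `p_threshold`, otherwise published with probability
#'   `retain_prob`. `retain_prob = 1` reproduces no bias, `0` total
#'   suppression of "negative" studies.
#' @param p_threshold One-sided significance cut (default 0.05).
#' @param retain_prob Probability in [0, 1] that a non-significant study is
#'   published.
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(mode = c("none", "p_step"), p_threshold = 0.05,
                           retain_prob = 1) {
  mode <- match.arg(mode)
  if (retain_prob < 0 || retain_prob > 1) {
    stop("retain_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, p_threshold = p_threshold,
                 retain_prob = retain_prob),
            class = "selection_rule")
}

# draw once from a truncated law description (rejection sampling)
.draw_trunc <- function(d) {
  if (d$type == "fixed") return(d$value)
  for (i in 1:10000) {
    x <- switch(d$type,
                lognormal = rlnorm(1, d$meanlog, d$sdlog),
                beta = rbeta(1, d$shape1, d$shape2))
    if (!is.null(d$integer) && d$integer) x <- round(x)
    if (x >= d$min && x <= d$max) return(x)
  }
  stop("scenario validation error: truncation range unreachable", call. = FALSE)
}

#' Describe a simulation scenario for a meta-analysis corpus
#'
#' Defaults emulate the scale of published diagnostic accuracy
#' meta-analysis corpora: studies-per-meta lognormal with median ~13 and
#' IQR ~9-19 truncated to [4, 118]; per-study totals lognormal with median
#' 100 truncated to [20, 2000]; prevalence Beta(2, 2) truncated to
#' [0.05, 0.95].
#'
#' @param n_metas Number of meta-analyses.
#' @param ln_dor_true Underlying log diagnostic odds ratio (0 = an
#'   uninformative test; `log(81)` approx 4.39 is a high-accuracy test with
#'   sensitivity = specificity = 0.9 at the central threshold).
#' @param tau SD of per-study heterogeneity in the log DOR (>= 0).
#' @param sigma_theta SD of the per-study threshold shift (>= 0); moves
#'   sensitivity and specificity in opposite directions along a symmetric
#'   ROC at constant DOR.
#' @param k Studies per meta-analysis: `NULL` for the default lognormal
#'   law, or a fixed integer.
#' @param k_distribution,n_distribution,prevalence_distribution Law
#'   descriptions (lists with `type` and parameters); override for custom
#'   designs.
#' @param suppression A [selection_rule()].
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the scenario including the seed.
#' @return A `simulation_scenario` object.
#' @details Per-study generative model: draw total size n and prevalence,
#'   set `n1 = round(prev * n)` (clamped so both groups are >= 1); draw
#'   study log DOR `L_i ~ N(ln_dor_true, tau^2)` and threshold shift
#'   `theta_i ~ N(0, sigma_theta^2)`; set `logit(sens) = theta_i + L_i / 2`
#'   and `logit(1 - spec) = theta_i - L_i / 2`, so
#'   `logit(sens) - logit(1 - spec) = L_i` exactly (constant-DOR symmetric
#'   ROC); draw `tp ~ Bin(n1, sens)`, `tn ~ Bin(n2, spec)`.
#'
#'   Random numbers are consumed in a documented, stable order: per meta
#'   the study count, then per study attempt n, prevalence, L_i, theta_i,
#'   tp, tn, and (only when the selection rule actually needs one) a
#'   publication uniform. A `p_step` rule with `retain_prob = 1` draws no
#'   uniforms and is stream-identical to no selection.
#' @export
simulation_scenario <- function(n_metas = 92, ln_dor_true = 0, tau = 0,
                                sigma_theta = 0, k = NULL,
                                k_distribution = NULL, n_distribution = NULL,
                                prevalence_distribution = NULL,
                                suppression = selection_rule("none"),
                                seed = 1L) {
  if (tau < 0 || sigma_theta < 0) stop("SDs must be >= 0", call. = FALSE)
  if (is.null(k_distribution)) {
    k_distribution <- if (!is.null(k)) {
      list(type = "fixed", value = as.integer(k))
    } else {
      list(type = "lognormal", meanlog = log(13), sdlog = 0.55,
           min = 4, max = 118, integer = TRUE)
    }
  }
  if (is.null(n_distribution)) {
    n_distribution <- list(type = "lognormal", meanlog = log(100),
                           sdlog = 0.6, min = 20, max = 2000, integer = TRUE)
  }
  if (is.null(prevalence_distribution)) {
    prevalence_distribution <- list(type = "beta", shape1 = 2, shape2 = 2,
                                    min = 0.05, max = 0.95)
  }
  structure(list(n_metas = as.integer(n_metas), ln_dor_true = ln_dor_true,
                 tau = tau, sigma_theta = sigma_theta,
                 k_distribution = k_distribution,
                 n_distribution = n_distribution,
                 prevalence_distribution = prevalence_distribution,
                 suppression = suppression, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Simulate one primary study
#'
#' Uses the current RNG state (call `set.seed()` or use
#' [simulate_corpus()] for reproducibility).
#'
#' @param scenario A [simulation_scenario()].
#' @param study_id Label for the study.
#' @return A [study_table()] with attributes `sens`, `spec`, `ln_dor_i`
#'   and `theta_i` recording the study-level truth.
#' @export
simulate_study <- function(scenario, study_id = "s1") {
  n <- .draw_trunc(scenario$n_distribution)
  prev <- .draw_trunc(scenario$prevalence_distribution)
  n1 <- max(1L, min(n - 1L, as.integer(round(prev * n))))
  n2 <- n - n1
  L <- rnorm(1, scenario$ln_dor_true, scenario$tau)
  theta <- rnorm(1, 0, scenario$sigma_theta)
  sens <- plogis(theta + L / 2)
  spec <- 1 - plogis(theta - L / 2)
  tp <- rbinom(1, n1, sens)
  tn <- rbinom(1, n2, spec)
  tab <- study_table(study_id, tp = tp, fp = n2 - tn, fn = n1 - tp, tn = tn)
  attr(tab, "sens") <- sens
  attr(tab, "spec") <- spec
  attr(tab, "ln_dor_i") <- L
  attr(tab, "theta_i") <- theta
  tab
}

#' Decide whether a simulated study is published
#'
#' Computes the one-sided Wald p-value for `lnDOR > 0` (continuity
#' correction 0.5 applied when any cell is zero) and applies the step
#' rule. A publication uniform is drawn only when the decision is actually
#' random (`p >= threshold` and `0 < retain_prob < 1`), so degenerate
#' rules do not disturb the random-number stream.
#'
#' @param study A [study_table()].
#' @param rule A [selection_rule()].
#' @return Logical: is the study published?
#' @export
apply_selection <- function(study, rule) {
  if (rule$mode == "none") return(TRUE)
  eff <- study_effect(study, continuity = 0.5)
  z <- eff$ln_dor / eff$se_ln_dor
  p_one <- pnorm(z, lower.tail = FALSE)
  if (p_one < rule$p_threshold) return(TRUE)
  if (rule$retain_prob >= 1) return(TRUE)
  if (rule$retain_prob <= 0) return(FALSE)
  runif(1) < rule$retain_prob
}

#' Simulate a corpus of meta-analyses with known truth
#'
#' For each meta-analysis a study count k is drawn, then studies are
#' simulated and passed through the selection rule until k published
#' studies are collected (mirroring real corpora, where k counts published
#' studies). A cap of `50 * k` attempts guards against infeasible
#' scenarios.
#'
#' @param scenario A [simulation_scenario()] (its `seed` drives all
#'   randomness; identical scenarios give bit-identical corpora).
#' @return A list: `corpus` (a [corpus()]) and `truth`, a data.frame with
#'   one row per meta (`meta_id`, `k`, `ln_dor_true`, `tau`,
#'   `sigma_theta`, `suppressed`, `n_attempts`).
#' @export
simulate_corpus <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  set.seed(scenario$seed)
  metas <- vector("list", scenario$n_metas)
  truth <- vector("list", scenario$n_metas)
  for (m in seq_len(scenario$n_metas)) {
    k <- .draw_trunc(scenario$k_distribution)
    studies <- vector("list", k)
    got <- 0L
    attempts <- 0L
    cap <- 50L * k
    while (got < k) {
      attempts <- attempts + 1L
      if (attempts > cap) {
        stop("scenario infeasibility: attempt cap (", cap,
             ") exceeded for meta ", m, call. = FALSE)
      }
      tab <- simulate_study(scenario, study_id = sprintf("s%03d", got + 1L))
      if (apply_selection(tab, scenario$suppression)) {
        got <- got + 1L
        studies[[got]] <- tab
      }
    }
    id <- sprintf("meta%03d", m)
    metas[[m]] <- meta_analysis(id, studies, label = "simulated")
    truth[[m]] <- data.frame(meta_id = id, k = k,
                             ln_dor_true = scenario$ln_dor_true,
                             tau = scenario$tau,
                             sigma_theta = scenario$sigma_theta,
                             suppressed = scenario$suppression$mode != "none" &&
                               scenario$suppression$retain_prob < 1,
                             n_attempts = attempts,
                             stringsAsFactors = FALSE)
  }
  list(corpus = corpus(metas, provenance = sprintf(
         "simulated (seed %d)", scenario$seed)),
       truth = do.call(rbind, truth))
}

#' Monte-Carlo operating characteristics of the asymmetry tests
#'
#' Simulates `n_replicates` meta-analyses under the scenario, runs each
#' enabled test on each replicate, and reports per-test rejection
#' proportions at `alpha` with exact (Clopper-Pearson) binomial 95%
#' confidence intervals. Replicates where a test failed are counted
#' separately and excluded from that test's denominator.
#'
#' @param scenario A [simulation_scenario()]; `n_metas` is ignored in
#'   favour of `n_replicates`.
#' @param n_replicates Number of simulated meta-analyses (>= 100).
#' @param tests Character subset of `c("begg", "egger", "deeks")`.
#' @param alpha Rejection level (default 0.05).
#' @param continuity Continuity constant for zero cells.
#' @return data.frame with one row per test: `test`, `n_ok`, `n_error`,
#'   `rejections`, `rate`, `ci_lo`, `ci_hi`.
#' @export
estimate_operating_characteristics <- function(scenario, n_replicates = 1000,
                                               tests = c("begg", "egger", "deeks"),
                                               alpha = 0.05,
                                               continuity = 0.5) {
  if (n_replicates < 100) stop("n_replicates must be >= 100", call. = FALSE)
  tests <- match.arg(tests, c("begg", "egger", "deeks"), several.ok = TRUE)
  one <- simulation_scenario(
    n_metas = 1L, ln_dor_true = scenario$ln_dor_true, tau = scenario$tau,
    sigma_theta = scenario$sigma_theta,
    k_distribution = scenario$k_distribution,
    n_distribution = scenario$n_distribution,
    prevalence_distribution = scenario$prevalence_distribution,
    suppression = scenario$suppression, seed = scenario$seed)
  set.seed(scenario$seed)
  rej <- matrix(NA, n_replicates, length(tests),
                dimnames = list(NULL, tests))
  for (r in seq_len(n_replicates)) {
    # inline one-meta simulation on the current stream
    k <- .draw_trunc(one$k_distribution)
    tp <- fp <- fn <- tn <- integer(k)
    got <- 0L; attempts <- 0L; cap <- 50L * k
    while (got < k) {
      attempts <- attempts + 1L
      if (attempts > cap) stop("scenario infeasibility: attempt cap exceeded",
                               call. = FALSE)
      tab <- simulate_study(one)
      if (apply_selection(tab, one$suppression)) {
        got <- got + 1L
        tp[got] <- tab$tp; fp[got] <- tab$fp
        fn[got] <- tab$fn; tn[got] <- tab$tn
      }
    }
    eff <- tryCatch(.effects_from_counts(tp, fp, fn, tn, continuity),
                    error = function(e) NULL)
    if (is.null(eff)) next
    for (t in tests) {
      res <- tryCatch(
        switch(t,
               begg = begg_test(eff, alpha = alpha, meta_id = "sim"),
               egger = egger_test(eff, alpha = alpha, meta_id = "sim"),
               deeks = deeks_test(eff, alpha = alpha, meta_id = "sim")),
        error = function(e) NULL)
      if (!is.null(res) && is.finite(res$p_value)) {
        rej[r, t] <- res$p_value < alpha
      }
    }
  }
  out <- lapply(tests, function(t) {
    ok <- !is.na(rej[, t])
    x <- sum(rej[ok, t])
    n <- sum(ok)
    ci <- if (n > 0) binom.test(x, n)$conf.int else c(NA_real_, NA_real_)
    data.frame(test = t, n_ok = n, n_error = n_replicates - n,
               rejections = x, rate = if (n > 0) x / n else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
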