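# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the code paths they check.

# effects container from bare vectors (bypasses 2x2 tables)
effects_df <- function(ln_dor, var_ln_dor, ess = rep(100, length(ln_dor)),
                       n_total = ess) {
  structure(data.frame(
    study_id = paste0("s", seq_along(ln_dor)),
    dor = exp(ln_dor), ln_dor = ln_dor,
    var_ln_dor = var_ln_dor, se_ln_dor = sqrt(var_ln_dor),
    ess = ess, inv_sqrt_ess = 1 / sqrt(ess),
    n_total = n_total, corrected = FALSE,
    stringsAsFactors = FALSE),
    class = c("study_effects", "data.frame"))
}

# random plausible effects for property tests
random_effects <- function(k) {
  v <- runif(k, 0.05, 2)
  effects_df(rnorm(k, 1, 1), v, ess = round(runif(k, 20, 500)))
}

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

# brute-force two-sided exact p for Kendall S by enumerating all rank
# permutations of y against fixed x (tie-free inputs)
brute_kendall_p <- function(x, y) {
  k <- length(x)
  rx <- rank(x)
  pair <- t(utils::combn(k, 2))
  s_of <- function(ry) sum(sign(rx[pair[, 2]] - rx[pair[, 1]]) *
                             sign(ry[pair[, 2]] - ry[pair[, 1]]))
  s_obs <- s_of(rank(y))
  perms <- all_perms(k)
  s_all <- apply(perms, 1, s_of)
  min(1, 2 * min(mean(s_all <= s_obs), mean(s_all >= s_obs)))
}

# closed-form weighted least squares slope test via normal equations
wls_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% beta
  s2 <- sum(w * resid^2) / (length(y) - 2)
  cov <- s2 * solve(XtWX)
  tval <- beta[2] / sqrt(cov[2, 2])
  list(slope = beta[2], t = tval,
       p = 2 * pt(-abs(tval), df = length(y) - 2))
}

# textbook DerSimonian-Laird oracle
dl_oracle <- function(y, v) {
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - mu_fe)^2)
  tau2 <- max(0, (Q - (length(y) - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  list(mu = sum(wr * y) / sum(wr), tau2 = tau2)
}

# small corpus with valid random tables
random_corpus <- function(n_metas = 3, k = 4) {
  metas <- lapply(seq_len(n_metas), function(m) {
    studies <- lapply(seq_len(k), function(s) {
      n1 <- sample(10:80, 1); n2 <- sample(10:80, 1)
      tp <- sample(1:(n1 - 1), 1); tn <- sample(1:(n2 - 1), 1)
      study_table(paste0("s", s), tp, n2 - tn, n1 - tp, tn)
    })
    meta_analysis(paste0("m", m), studies, label = paste("meta", m))
  })
  corpus(metas, provenance = "fixture")
}

# corpus-wide list of test results for concordance fixtures
corpus_results <- function(corp, config = run_config()) {
  out <- list()
  for (m in corp$metas) out <- c(out, unname(run_all_tests(m, config)))
  out
}
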