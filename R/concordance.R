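# Pairwise agreement between the significance calls of different
# asymmetry tests across a corpus of meta-analyses.

# save/restore the global RNG state around an internally seeded block
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Collate test results into a call matrix
#'
#' @param results A flat list of `bias_test_result` objects (e.g. from
#'   [run_all_tests()] applied over a corpus, concatenated).
#' @param alpha Significance level; a call is significant iff
#'   `p_value < alpha` (strictly: p exactly equal to alpha is not
#'   significant).
#' @return A `call_matrix`: matrices `p` and `sig` (meta x test; NA where
#'   the test did not run), a data.frame `excluded` of (meta_id, test,
#'   reason), and `alpha`.
#' @export
build_call_matrix <- function(results, alpha = 0.05) {
  if (inherits(results, "bias_test_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, as.data.frame))
  if (anyDuplicated(df[, c("meta_id", "test")])) {
    dup <- df[duplicated(df[, c("meta_id", "test")]), c("meta_id", "test")]
    stop("integrity error: duplicate (meta, test) entries: ",
         paste(paste(dup$meta_id, dup$test, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  metas <- unique(df$meta_id)
  tests <- unique(df$test)
  p <- matrix(NA_real_, length(metas), length(tests),
              dimnames = list(metas, tests))
  for (i in seq_len(nrow(df))) p[df$meta_id[i], df$test[i]] <- df$p_value[i]
  sig <- is.finite(p) & p < alpha
  sig[!is.finite(p)] <- NA
  bad <- !is.finite(df$p_value)
  excluded <- data.frame(meta_id = df$meta_id[bad], test = df$test[bad],
                         reason = ifelse(nzchar(df$notes[bad]), df$notes[bad],
                                         "test failed"),
                         stringsAsFactors = FALSE)
  structure(list(p = p, sig = sig, excluded = excluded, alpha = alpha),
            class = "call_matrix")
}

# Cohen's kappa with the large-sample (Fleiss-Cohen-Everitt) standard
# error, for an r x r agreement table of proportions.
.kappa_se <- function(pm, n) {
  r <- nrow(pm)
  pi_ <- rowSums(pm)
  p_j <- colSums(pm)
  po <- sum(diag(pm))
  pe <- sum(pi_ * p_j)
  kappa <- (po - pe) / (1 - pe)
  A <- sum(diag(pm) * (1 - (pi_ + p_j) * (1 - kappa))^2)
  B <- 0
  for (i in seq_len(r)) for (j in seq_len(r)) {
    if (i != j) B <- B + pm[i, j] * (p_j[i] + pi_[j])^2
  }
  B <- B * (1 - kappa)^2
  C <- (kappa - pe * (1 - kappa))^2
  se <- sqrt(max(0, A + B - C)) / ((1 - pe) * sqrt(n))
  list(kappa = kappa, po = po, pe = pe, se = se)
}

#' Pairwise concordance of two tests' significance calls
#'
#' Concordance is the proportion of meta-analyses where the two tests
#' agree (both significant or both not), chance-corrected by Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)`. With two categories, weighted and unweighted
#' kappa coincide. The 95% CI uses the asymptotic kappa standard error and
#' normal quantiles.
#'
#' @param matrix A `call_matrix` from [build_call_matrix()].
#' @param test_a,test_b Test labels (columns of the matrix). Only
#'   meta-analyses where both tests produced a call are used
#'   (pairwise complete-case).
#' @param ci `"asymptotic"` (default) or `"bootstrap"`: percentile
#'   interval from resampling meta-analyses, more trustworthy for small
#'   corpora.
#' @param n_boot,boot_seed Bootstrap replicates and seed (used only when
#'   `ci = "bootstrap"`).
#' @return A `concordance_result`: 2x2 `agreement_table`
#'   (rows = `test_a` sig/notsig, cols = `test_b`), `concordance_pct`,
#'   `kappa`, `kappa_ci`, `n`, plus flags in `notes`.
#' @export
pairwise_concordance <- function(matrix, test_a, test_b,
                                 ci = c("asymptotic", "bootstrap"),
                                 n_boot = 2000, boot_seed = 1L) {
  ci <- match.arg(ci)
  stopifnot(inherits(matrix, "call_matrix"))
  for (t in c(test_a, test_b)) {
    if (!t %in% colnames(matrix$sig)) stop("unknown test: ", t, call. = FALSE)
  }
  a <- matrix$sig[, test_a]
  b <- matrix$sig[, test_b]
  keep <- !is.na(a) & !is.na(b)
  n <- sum(keep)
  if (n < 2) stop("insufficient data: < 2 meta-analyses with both calls",
                  call. = FALSE)
  a <- a[keep]; b <- b[keep]
  tab <- base::matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                      2, 2, byrow = TRUE,
                      dimnames = list(c("a_sig", "a_notsig"),
                                      c("b_sig", "b_notsig")))
  pm <- tab / n
  notes <- character()
  pe <- sum(rowSums(pm) * colSums(pm))
  if (pe >= 1) {
    kap <- list(kappa = NA_real_, po = sum(diag(pm)), pe = pe, se = NA_real_)
    notes <- "kappa undefined: no chance-disagreement (constant marginals)"
  } else {
    kap <- .kappa_se(pm, n)
  }
  kappa_ci <- if (!is.finite(kap$se)) {
    c(NA_real_, NA_real_)
  } else if (ci == "asymptotic") {
    kap$kappa + c(-1, 1) * qnorm(0.975) * kap$se
  } else {
    boot_kappa <- function(ai, bi) {
      pmb <- base::matrix(c(mean(ai & bi), mean(ai & !bi),
                            mean(!ai & bi), mean(!ai & !bi)), 2, 2,
                          byrow = TRUE)
      pe_b <- sum(rowSums(pmb) * colSums(pmb))
      if (pe_b >= 1) return(NA_real_)
      (sum(diag(pmb)) - pe_b) / (1 - pe_b)
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(boot_seed)
    reps <- replicate(n_boot, {
      idx <- sample.int(n, n, replace = TRUE)
      boot_kappa(a[idx], b[idx])
    })
    unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(test_a = test_a, test_b = test_b,
                 agreement_table = tab,
                 concordance_pct = 100 * kap$po,
                 kappa = kap$kappa,
                 kappa_se = kap$se,
                 kappa_ci = kappa_ci,
                 n = n, notes = notes),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance> ", x$test_a, " vs ", x$test_b, ": ",
      round(x$concordance_pct, 1), "% (kappa = ",
      signif(x$kappa, 3), "; 95% CI ", signif(x$kappa_ci[1], 3), " to ",
      signif(x$kappa_ci[2], 3), "; n = ", x$n, ")\n", sep = "")
  print(x$agreement_table)
  invisible(x)
}

#' @export
as.data.frame.concordance_result <- function(x, ...) {
  data.frame(test_a = x$test_a, test_b = x$test_b,
             both_sig = x$agreement_table[1, 1],
             a_only = x$agreement_table[1, 2],
             b_only = x$agreement_table[2, 1],
             neither = x$agreement_table[2, 2],
             concordance_pct = x$concordance_pct,
             kappa = x$kappa, kappa_lo = x$kappa_ci[1],
             kappa_hi = x$kappa_ci[2], n = x$n,
             stringsAsFactors = FALSE)
}

#' Scatter plot of two tests' p-values across a corpus
#'
#' One point per meta-analysis on the unit square, with dotted gridlines at
#' the significance level on both axes and the concordance/kappa summary
#' in the margin.
#'
#' @param matrix A `call_matrix`.
#' @param test_x,test_y Tests on the x and y axes.
#' @param path Output image path (`.png`, `.svg`, `.pdf`).
#' @param alpha Gridline position; defaults to the matrix alpha.
#' @return `path`, invisibly; the annotation string is attached as
#'   attribute `annotation`.
#' @export
pvalue_scatter <- function(matrix, test_x, test_y, path,
                           alpha = matrix$alpha) {
  stopifnot(inherits(matrix, "call_matrix"))
  px <- matrix$p[, test_x]
  py <- matrix$p[, test_y]
  keep <- is.finite(px) & is.finite(py)
  if (!any(keep)) stop("render error: no meta-analysis with both p-values",
                       call. = FALSE)
  ann <- tryCatch({
    cc <- pairwise_concordance(matrix, test_x, test_y)
    sprintf("concordance %.0f%% (kappa = %.3f)", cc$concordance_pct, cc$kappa)
  }, error = function(e) "")
  .open_device(path)
  on.exit(dev.off())
  plot(px[keep], py[keep], xlim = c(0, 1), ylim = c(0, 1),
       xlab = paste(test_x, "p-value"), ylab = paste(test_y, "p-value"),
       main = paste0(test_y, " vs ", test_x), pch = 19)
  abline(v = alpha, h = alpha, lty = 3)
  if (nzchar(ann)) mtext(ann, side = 3, line = 0.2, cex = 0.8)
  out <- path
  attr(out, "annotation") <- ann
  invisible(out)
}
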