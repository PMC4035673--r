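# Logistic moderator regression: is concordance between two asymmetry
# tests associated with meta-analysis characteristics (pooled DOR above the
# high-accuracy cut, number of studies, number of patients)?

#' Build per-meta moderator records for one test pair
#'
#' @param matrix A `call_matrix` from [build_call_matrix()].
#' @param corpus The [corpus()] the calls were computed from.
#' @param pooled Named list of [pool_ln_dor()] results, one per meta_id.
#' @param pair Character vector of two test labels.
#' @param dor_threshold High-accuracy cut on the pooled DOR (default 38).
#' @param dor_inclusive If `TRUE` (default) the indicator is
#'   `pooled DOR >= threshold`, else strictly greater.
#' @return data.frame of class `moderator_records`: one row per
#'   meta-analysis with both calls, columns `meta_id`, `concordant`,
#'   `n_participants`, `n_studies`, `dor_gt_38`.
#' @export
build_moderator_records <- function(matrix, corpus, pooled, pair,
                                    dor_threshold = 38,
                                    dor_inclusive = TRUE) {
  stopifnot(inherits(matrix, "call_matrix"), length(pair) == 2)
  a <- matrix$sig[, pair[1]]
  b <- matrix$sig[, pair[2]]
  keep <- !is.na(a) & !is.na(b)
  ids <- rownames(matrix$sig)[keep]
  rows <- lapply(ids, function(id) {
    m <- corpus$metas[[id]]
    pe <- pooled[[id]]
    if (is.null(m) || is.null(pe)) {
      stop("integrity error: missing ",
           if (is.null(m)) "meta" else "pooled effect",
           " for '", id, "'", call. = FALSE)
    }
    data.frame(meta_id = id,
               concordant = a[id] == b[id],
               n_participants = sum(m$studies$tp + m$studies$fp +
                                      m$studies$fn + m$studies$tn),
               n_studies = nrow(m$studies),
               dor_gt_38 = if (dor_inclusive) pe$dor_pooled >= dor_threshold
                           else pe$dor_pooled > dor_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pair") <- pair
  class(out) <- c("moderator_records", "data.frame")
  out
}

#' Univariable logistic regression of concordance on one factor
#'
#' Fits `concordant ~ factor` by maximum likelihood (IRLS, convergence
#' tolerance 1e-10, at most 100 iterations) and reports the odds ratio
#' `exp(beta)` with a 95% Wald interval. For a single binary predictor the
#' MLE equals the sample cross-product odds ratio of the 2x2 table.
#' Complete or quasi-complete separation (non-convergence or |beta| > 15)
#' is detected and flagged; no odds ratio is reported in that case.
#'
#' @param records A `moderator_records` data.frame.
#' @param factor One of `"dor_gt_38"`, `"n_studies"`, `"n_participants"`.
#' @param min_n Minimum number of records required (default 10).
#' @return A `moderator_fit`: `pair`, `factor`, `odds_ratio`, `ci95`,
#'   `beta`, `se`, `converged`, `n`, `notes`.
#' @export
fit_logistic <- function(records, factor = c("dor_gt_38", "n_studies",
                                             "n_participants"),
                         min_n = 10) {
  factor <- match.arg(factor)
  n <- nrow(records)
  if (n < min_n) stop("insufficient data: need >= ", min_n, " records",
                      call. = FALSE)
  y <- as.integer(records$concordant)
  if (length(unique(y)) < 2) {
    stop("non-identifiable: outcome is constant", call. = FALSE)
  }
  x <- as.numeric(records[[factor]])
  if (length(unique(x)) < 2) {
    stop("non-identifiable: predictor '", factor, "' is constant", call. = FALSE)
  }
  fit <- suppressWarnings(
    glm(y ~ x, family = binomial(),
        control = stats::glm.control(epsilon = 1e-10, maxit = 100))
  )
  beta <- unname(coef(fit)[2])
  se <- sqrt(diag(vcov(fit)))[2]
  separated <- !fit$converged || abs(beta) > 15
  structure(list(pair = attr(records, "pair") %||% c(NA, NA),
                 factor = factor,
                 odds_ratio = if (separated) NA_real_ else exp(beta),
                 ci95 = if (separated) c(NA_real_, NA_real_) else
                   exp(beta + c(-1, 1) * qnorm(0.975) * se),
                 beta = beta, se = unname(se),
                 converged = !separated, n = n,
                 notes = if (separated) "separation detected: no OR reported"
                         else character()),
            class = "moderator_fit")
}

#' @export
print.moderator_fit <- function(x, ...) {
  cat("<moderator_fit> ", paste(x$pair, collapse = "-"), " ~ ", x$factor,
      ": OR = ", signif(x$odds_ratio, 3), " (95% CI ",
      signif(x$ci95[1], 3), " to ", signif(x$ci95[2], 3), "), n = ",
      x$n, "\n", sep = "")
  if (length(x$notes)) cat("  notes:", x$notes, "\n")
  invisible(x)
}

#' @export
as.data.frame.moderator_fit <- function(x, ...) {
  data.frame(pair = paste(x$pair, collapse = "-"), factor = x$factor,
             odds_ratio = x$odds_ratio, ci_lo = x$ci95[1], ci_hi = x$ci95[2],
             converged = x$converged, n = x$n,
             notes = paste(x$notes, collapse = "; "),
             stringsAsFactors = FALSE)
}
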