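#' Effective sample size of a diagnostic accuracy study
#'
#' The effective sample size `ESS = 4 n1 n2 / (n1 + n2)` is the size of a
#' balanced study carrying the same information as a study with `n1`
#' diseased and `n2` non-diseased participants. It equals the total sample
#' size when the groups are balanced and is strictly smaller otherwise,
#' penalizing the unequal group sizes typical of accuracy studies.
#'
#' @param n_diseased,n_nondiseased Group sizes (>= 1).
#' @return The effective sample size (numeric, in participants).
#' @examples
#' ess(50, 50)  # 100: balanced design
#' ess(90, 10)  # 36
#' @export
ess <- function(n_diseased, n_nondiseased) {
  if (any(n_diseased < 1) || any(n_nondiseased < 1)) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  4 * n_diseased * n_nondiseased / (n_diseased + n_nondiseased)
}

#' Per-study effect measures for a 2x2 accuracy table
#'
#' Computes the diagnostic odds ratio `DOR = (tp * tn) / (fp * fn)`, its
#' natural log, the Woolf variance `1/tp + 1/fp + 1/fn + 1/tn`, and the
#' effective sample size, for one study.
#'
#' @param table A [study_table()].
#' @param continuity Constant added to all four cells when any cell is zero
#'   (default 0.5). Zero disables the correction, in which case a table with
#'   an empty cell is an error.
#' @param always_correct If `TRUE`, add `continuity` to every table rather
#'   than only to tables with a zero cell.
#' @return A one-row data.frame of class `study_effects` with columns
#'   `study_id`, `dor`, `ln_dor`, `var_ln_dor`, `se_ln_dor`, `ess`,
#'   `inv_sqrt_ess`, `n_total`, `corrected`.
#' @details The effective sample size is always computed from the
#'   uncorrected group sizes: it is a property of the study design, not of
#'   the estimate.
#' @examples
#' study_effect(study_table("s", 9, 1, 1, 9))
#' @export
study_effect <- function(table, continuity = 0.5, always_correct = FALSE) {
  stopifnot(inherits(table, "study_table"))
  if (continuity < 0) stop("continuity must be >= 0", call. = FALSE)
  cells <- c(table$tp, table$fp, table$fn, table$tn)
  corrected <- always_correct || any(cells == 0)
  if (corrected) {
    if (continuity == 0 && any(cells == 0)) {
      stop("degenerate effect for study '", table$study_id,
           "': zero cell with continuity = 0", call. = FALSE)
    }
    cells <- cells + continuity
  }
  dor <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  v <- sum(1 / cells)
  e <- ess(table$n_diseased, table$n_nondiseased)
  structure(
    data.frame(study_id = table$study_id,
               dor = dor, ln_dor = log(dor),
               var_ln_dor = v, se_ln_dor = sqrt(v),
               ess = e, inv_sqrt_ess = 1 / sqrt(e),
               n_total = table$n_diseased + table$n_nondiseased,
               corrected = corrected,
               stringsAsFactors = FALSE),
    class = c("study_effects", "data.frame")
  )
}

#' Effect measures for every study of a meta-analysis
#'
#' @param meta A [meta_analysis()].
#' @inheritParams study_effect
#' @return A `study_effects` data.frame, one row per study.
#' @export
meta_effects <- function(meta, continuity = 0.5, always_correct = FALSE) {
  stopifnot(inherits(meta, "meta_analysis"))
  s <- meta$studies
  out <- do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
    study_effect(study_table(s$study_id[i], s$tp[i], s$fp[i], s$fn[i], s$tn[i]),
                 continuity = continuity, always_correct = always_correct)
  }))
  rownames(out) <- NULL
  attr(out, "meta_id") <- meta$meta_id
  out
}

# Vectorized effects from raw count vectors; fast path for simulation.
# Semantics identical to study_effect() row by row.
.effects_from_counts <- function(tp, fp, fn, tn, continuity = 0.5,
                                 study_id = paste0("s", seq_along(tp))) {
  n1 <- tp + fn
  n2 <- fp + tn
  zero <- tp == 0 | fp == 0 | fn == 0 | tn == 0
  if (continuity == 0 && any(zero)) {
    stop("degenerate effect: zero cell with continuity = 0", call. = FALSE)
  }
  cc <- ifelse(zero, continuity, 0)
  a <- tp + cc; b <- fp + cc; c <- fn + cc; d <- tn + cc
  dor <- (a * d) / (b * c)
  v <- 1 / a + 1 / b + 1 / c + 1 / d
  e <- 4 * n1 * n2 / (n1 + n2)
  structure(
    data.frame(study_id = study_id, dor = dor, ln_dor = log(dor),
               var_ln_dor = v, se_ln_dor = sqrt(v),
               ess = e, inv_sqrt_ess = 1 / sqrt(e),
               n_total = n1 + n2, corrected = zero,
               stringsAsFactors = FALSE),
    class = c("study_effects", "data.frame")
  )
}

#' Pool log diagnostic odds ratios across studies
#'
#' Inverse-variance fixed-effect pooling, or DerSimonian-Laird random
#' effects with the usual moment estimator of the between-study variance
#' `tau^2` (truncated at zero).
#'
#' @param effects A `study_effects` data.frame (>= 2 studies).
#' @param method `"dersimonian-laird"` (default) or `"fixed"`.
#' @return A list of class `pooled_effect`: `ln_dor_pooled`, `dor_pooled`,
#'   `tau2`, `k`, `method`.
#' @export
pool_ln_dor <- function(effects, method = c("dersimonian-laird", "fixed")) {
  method <- match.arg(method)
  y <- effects$ln_dor
  v <- effects$var_ln_dor
  k <- length(y)
  if (k < 2) stop("insufficient data: pooling needs >= 2 studies", call. = FALSE)
  w <- 1 / v
  mu_fe <- sum(w * y) / sum(w)
  tau2 <- 0
  if (method == "dersimonian-laird") {
    Q <- sum(w * (y - mu_fe)^2)
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - (k - 1)) / C)
  }
  w_star <- 1 / (v + tau2)
  mu <- sum(w_star * y) / sum(w_star)
  structure(list(ln_dor_pooled = mu, dor_pooled = exp(mu),
                 tau2 = tau2, k = k, method = method),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat("<pooled_effect> ", x$method, ": DOR = ", signif(x$dor_pooled, 4),
      " (lnDOR = ", signif(x$ln_dor_pooled, 4), "), tau2 = ",
      signif(x$tau2, 4), ", k = ", x$k, "\n", sep = "")
  invisible(x)
}
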