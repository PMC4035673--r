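# End-to-end orchestration: corpus -> effects -> asymmetry tests ->
# concordance -> moderators -> tables and figures.

#' Pipeline run configuration
#'
#' @param alpha Significance level for all tests (default 0.05; a call is
#'   significant iff p < alpha, strictly).
#' @param begg_variant `"standardized"` (default) or `"naive"`.
#' @param continuity Continuity constant for zero cells (default 0.5).
#' @param min_k_warn Results from meta-analyses with fewer studies carry a
#'   low-power note (default 10).
#' @param pooling `"dersimonian-laird"` (default) or `"fixed"`, used for
#'   the pooled-DOR moderator.
#' @param dor_threshold High-accuracy cut on the pooled DOR (default 38).
#' @param dor_inclusive Indicator is `>=` threshold when `TRUE` (default).
#' @param tests Enabled tests, in order.
#' @param render_funnels Also render one funnel plot (lnDOR vs 1/sqrt(ESS))
#'   per meta-analysis (default `FALSE`; can be slow for large corpora).
#' @param image_format `"png"`, `"svg"` or `"pdf"`.
#' @param seed Seed (only consumed where a downstream option is stochastic).
#' @return A `run_config` object.
#' @export
run_config <- function(alpha = 0.05, begg_variant = "standardized",
                       continuity = 0.5, min_k_warn = 10,
                       pooling = "dersimonian-laird", dor_threshold = 38,
                       dor_inclusive = TRUE,
                       tests = c("begg", "egger", "deeks"),
                       render_funnels = FALSE, image_format = "png",
                       seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (dor_threshold <= 0) stop("dor_threshold must be > 0", call. = FALSE)
  structure(list(alpha = alpha, begg_variant = begg_variant,
                 continuity = continuity, min_k_warn = min_k_warn,
                 pooling = pooling, dor_threshold = dor_threshold,
                 dor_inclusive = dor_inclusive, tests = tests,
                 render_funnels = isTRUE(render_funnels),
                 image_format = image_format, seed = as.integer(seed)),
            class = "run_config")
}

#' Per-test significance summary of a corpus run
#'
#' @param results Flat list of `bias_test_result` objects.
#' @return data.frame with one row per test: counts and percentages (to
#'   one decimal) of meta-analyses where small study-effects were
#'   identified / not identified, and the total, plus a preformatted
#'   display string per row.
#' @export
summarize_significance <- function(results) {
  df <- do.call(rbind, lapply(results, as.data.frame))
  df <- df[is.finite(df$p_value), ]
  if (nrow(df) == 0) stop("no successful test results to summarize", call. = FALSE)
  out <- lapply(unique(df$test), function(t) {
    d <- df[df$test == t, ]
    n <- nrow(d)
    sig <- sum(d$significant)
    data.frame(test = t, identified = sig,
               identified_pct = round(100 * sig / n, 1),
               not_identified = n - sig,
               not_identified_pct = round(100 * (n - sig) / n, 1),
               total = n,
               display = sprintf("%d (%.1f) / %d (%.1f) / %d",
                                 sig, 100 * sig / n,
                                 n - sig, 100 * (n - sig) / n, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full comparison pipeline on a corpus
#'
#' Applies every enabled asymmetry test to every meta-analysis, collates
#' significance calls, computes all pairwise concordances (kappa, CI,
#' agreement tables) and the moderator regressions (pooled DOR above the
#' threshold, number of studies, number of participants) for every pair,
#' and writes tables, figures and a machine-readable report.
#'
#' @param corpus_path Path to a corpus file ([read_corpus()]) or a
#'   [corpus()] object.
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return A `corpus_report` (invisibly the same structure written to
#'   `report.json`): significance summary, concordance results, moderator
#'   grid, exclusions, figure paths, config echo.
#' @details The run is deterministic given corpus + config. Outputs:
#'   `report.json`, `table2.csv` (per-test summary), `concordance.csv`,
#'   `table3.csv` (moderator grid), `exclusions.csv`, and one p-value
#'   scatter per test pair. Per-meta failures are recorded as exclusions,
#'   never fatal.
#' @export
run_pipeline <- function(corpus_path, config = run_config(),
                         out_dir = "dtabias-report") {
  corp <- if (inherits(corpus_path, "corpus")) corpus_path
          else read_corpus(corpus_path)
  if (length(corp$metas) == 0) stop("empty corpus", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  for (m in corp$metas) {
    results <- c(results, unname(run_all_tests(m, config)))
  }
  cm <- build_call_matrix(results, alpha = config$alpha)

  summary_df <- tryCatch(summarize_significance(results),
                         error = function(e) NULL)

  pooled <- lapply(corp$metas, function(m) {
    tryCatch(pool_ln_dor(meta_effects(m, continuity = config$continuity),
                         method = config$pooling),
             error = function(e) NULL)
  })

  pairs <- utils::combn(config$tests, 2, simplify = FALSE)
  conc <- list()
  figures <- character()
  for (pr in pairs) {
    key <- paste(pr, collapse = "-")
    conc[[key]] <- tryCatch(pairwise_concordance(cm, pr[1], pr[2]),
                            error = function(e) e)
    fig <- file.path(out_dir, paste0("pvalues_", key, ".",
                                     config$image_format))
    ok <- tryCatch({
      pvalue_scatter(cm, pr[1], pr[2], fig, alpha = config$alpha); TRUE
    }, error = function(e) FALSE)
    if (ok) figures <- c(figures, fig)
  }

  factors <- c("dor_gt_38", "n_studies", "n_participants")
  moderator_rows <- list()
  for (pr in pairs) {
    key <- paste(pr, collapse = "-")
    recs <- tryCatch(
      build_moderator_records(cm, corp, pooled, pr,
                              dor_threshold = config$dor_threshold,
                              dor_inclusive = config$dor_inclusive),
      error = function(e) NULL)
    for (f in factors) {
      fit <- if (is.null(recs)) NULL else
        tryCatch(fit_logistic(recs, f), error = function(e) e)
      moderator_rows[[paste(key, f)]] <-
        if (is.null(fit) || inherits(fit, "error")) {
          data.frame(pair = key, factor = f, odds_ratio = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, converged = FALSE,
                     n = if (is.null(recs)) 0L else nrow(recs),
                     notes = if (is.null(fit)) "no records"
                             else conditionMessage(fit),
                     stringsAsFactors = FALSE)
        } else as.data.frame(fit)
    }
  }
  moderators_df <- do.call(rbind, moderator_rows)
  rownames(moderators_df) <- NULL

  if (config$render_funnels) {
    for (m in corp$metas) {
      fd <- tryCatch(funnel_coordinates(m, funnel_spec(),
                                        continuity = config$continuity),
                     error = function(e) NULL)
      if (!is.null(fd) && nrow(fd$points) > 0) {
        fig <- file.path(out_dir, paste0("funnel_", m$meta_id, ".",
                                         config$image_format))
        ok <- tryCatch({render_funnel(fd, fig); TRUE},
                       error = function(e) FALSE)
        if (ok) figures <- c(figures, fig)
      }
    }
  }

  conc_df <- do.call(rbind, lapply(conc[!vapply(conc, inherits, TRUE, "error")],
                                   as.data.frame))
  if (!is.null(conc_df)) rownames(conc_df) <- NULL

  report <- structure(list(
    n_metas = length(corp$metas),
    significance_summary = summary_df,
    concordance = conc_df,
    moderators = moderators_df,
    exclusions = cm$excluded,
    figures = figures,
    config = unclass(config),
    package_version = as.character(utils::packageVersion("dtabias"))
  ), class = "corpus_report")

  if (!is.null(summary_df)) {
    write.csv(summary_df, file.path(out_dir, "table2.csv"), row.names = FALSE)
  }
  if (!is.null(conc_df)) {
    write.csv(conc_df, file.path(out_dir, "concordance.csv"), row.names = FALSE)
  }
  write.csv(moderators_df, file.path(out_dir, "table3.csv"), row.names = FALSE)
  write.csv(cm$excluded, file.path(out_dir, "exclusions.csv"), row.names = FALSE)
  jsonlite::write_json(.report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(report)
}

# figure paths are stored relative to the output directory so that reruns
# into different directories produce byte-identical reports
.report_to_json <- function(report) {
  report$figures <- basename(report$figures)
  list(n_metas = report$n_metas,
       significance_summary = report$significance_summary,
       concordance = report$concordance,
       moderators = report$moderators,
       exclusions = report$exclusions,
       figures = report$figures,
       config = report$config,
       package_version = report$package_version)
}

#' @export
print.corpus_report <- function(x, ...) {
  cat("<corpus_report> ", x$n_metas, " meta-analyses\n", sep = "")
  if (!is.null(x$significance_summary)) {
    cat("\nSmall study-effects identified / not identified / total:\n")
    for (i in seq_len(nrow(x$significance_summary))) {
      cat(sprintf("  %-6s %s\n", x$significance_summary$test[i],
                  x$significance_summary$display[i]))
    }
  }
  if (!is.null(x$concordance)) {
    cat("\nPairwise concordance:\n")
    for (i in seq_len(nrow(x$concordance))) {
      cat(sprintf("  %s-%s: %.0f%% (kappa = %.3f)\n",
                  x$concordance$test_a[i], x$concordance$test_b[i],
                  x$concordance$concordance_pct[i], x$concordance$kappa[i]))
    }
  }
  cat("\n", nrow(x$exclusions), " exclusions; ", length(x$figures),
      " figures\n", sep = "")
  invisible(x)
}
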