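#' Construct a primary-study 2x2 accuracy table
#'
#' A diagnostic accuracy study cross-classifies participants by disease
#' status (reference standard) and index-test result, yielding counts of
#' true positives, false positives, false negatives and true negatives.
#'
#' @param study_id Character label, unique within a meta-analysis.
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return An object of class `study_table`: a named list with the four
#'   counts and the derived group sizes `n_diseased = tp + fn`,
#'   `n_nondiseased = fp + tn`.
#' @details Both groups must contain at least one participant: a study with
#'   no diseased (or no non-diseased) subjects carries no information on
#'   sensitivity (or specificity) and is rejected.
#' @examples
#' study_table("s1", tp = 9, fp = 1, fn = 1, tn = 9)
#' @export
study_table <- function(study_id, tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("study '", study_id, "': counts must be non-negative integers", call. = FALSE)
  }
  if (tp + fn < 1) {
    stop("study '", study_id, "': no diseased participants (tp + fn = 0)", call. = FALSE)
  }
  if (fp + tn < 1) {
    stop("study '", study_id, "': no non-diseased participants (fp + tn = 0)", call. = FALSE)
  }
  structure(
    list(study_id = as.character(study_id),
         tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn),
         n_diseased = as.integer(tp + fn),
         n_nondiseased = as.integer(fp + tn)),
    class = "study_table"
  )
}

#' Reconstruct a 2x2 table from group sizes and accuracy fractions
#'
#' Published reviews often report sensitivity and specificity with the
#' numbers of diseased and non-diseased participants rather than raw
#' counts; the 2x2 table is then recovered by arithmetic.
#'
#' @param n_diseased,n_nondiseased Group sizes (>= 1).
#' @param sensitivity,specificity Fractions in [0, 1].
#' @param study_id Label for the resulting table.
#' @return A `study_table`. The attribute `rounding` records the rule used
#'   (`"half-to-even"`).
#' @details `tp = round(sensitivity * n_diseased)` and
#'   `tn = round(specificity * n_nondiseased)` with round-half-to-even
#'   (banker's rounding, R's `round()`), a deterministic rule that is
#'   unbiased over a corpus; `fn` and `fp` are the complements.
#' @examples
#' reconstruct_table(100, 50, 0.9, 0.8)  # tp 90, fn 10, tn 40, fp 10
#' reconstruct_table(7, 9, 0.5, 0.5)     # 3.5 -> 4, 4.5 -> 4
#' @export
reconstruct_table <- function(n_diseased, n_nondiseased, sensitivity, specificity,
                              study_id = "reconstructed") {
  if (n_diseased < 1 || n_nondiseased < 1) {
    stop("group sizes must be >= 1", call. = FALSE)
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  tp <- round(sensitivity * n_diseased)
  tn <- round(specificity * n_nondiseased)
  tab <- study_table(study_id, tp = tp, fp = n_nondiseased - tn,
                     fn = n_diseased - tp, tn = tn)
  attr(tab, "rounding") <- "half-to-even"
  tab
}

#' Construct a meta-analysis of 2x2 tables
#'
#' @param meta_id Character label, unique within a corpus.
#' @param studies List of [study_table()] objects (or a data.frame with
#'   columns `study_id`, `tp`, `fp`, `fn`, `tn`).
#' @param label Free-text description of the index test / target condition.
#' @return An object of class `meta_analysis` holding the studies as a
#'   data.frame with one row per study.
#' @export
meta_analysis <- function(meta_id, studies, label = "") {
  if (is.data.frame(studies)) {
    need <- c("study_id", "tp", "fp", "fn", "tn")
    if (!all(need %in% names(studies))) {
      stop("studies data.frame needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    studies <- lapply(seq_len(nrow(studies)), function(i) {
      with(studies[i, ], study_table(study_id, tp, fp, fn, tn))
    })
  }
  if (length(studies) < 1) {
    stop("meta-analysis '", meta_id, "' has no studies", call. = FALSE)
  }
  ids <- vapply(studies, `[[`, character(1), "study_id")
  if (anyDuplicated(ids)) {
    stop("meta-analysis '", meta_id, "': duplicate study_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    study_id = ids,
    tp = vapply(studies, `[[`, integer(1), "tp"),
    fp = vapply(studies, `[[`, integer(1), "fp"),
    fn = vapply(studies, `[[`, integer(1), "fn"),
    tn = vapply(studies, `[[`, integer(1), "tn"),
    stringsAsFactors = FALSE
  )
  structure(list(meta_id = as.character(meta_id), label = as.character(label),
                 studies = df),
            class = "meta_analysis")
}

#' @export
print.meta_analysis <- function(x, ...) {
  cat("<meta_analysis>", x$meta_id,
      if (nzchar(x$label)) paste0("(", x$label, ")") else "",
      "-", nrow(x$studies), "studies\n")
  print(head(x$studies, 5))
  if (nrow(x$studies) > 5) cat("...\n")
  invisible(x)
}

#' Construct a corpus of meta-analyses
#'
#' @param metas List of [meta_analysis()] objects.
#' @param provenance Free-text source description.
#' @return An object of class `corpus`.
#' @export
corpus <- function(metas, provenance = "") {
  ids <- vapply(metas, `[[`, character(1), "meta_id")
  if (anyDuplicated(ids)) {
    stop("duplicate meta_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(metas) <- ids
  structure(list(metas = metas, provenance = as.character(provenance)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  k <- vapply(x$metas, function(m) nrow(m$studies), integer(1))
  cat("<corpus> ", length(x$metas), " meta-analyses, ",
      sum(k), " studies (k: ",
      if (length(k)) paste0(min(k), "-", max(k)) else "none", ")\n", sep = "")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$metas)

# canonical long-format columns
.corpus_cols_counts <- c("meta_id", "study_id", "tp", "fp", "fn", "tn")
.corpus_cols_fracs  <- c("meta_id", "study_id", "n_diseased", "n_nondiseased",
                         "sensitivity", "specificity")

#' Read a corpus of meta-analyses from delimited text
#'
#' Long format, one row per primary study. Two column layouts are accepted:
#' raw counts (`tp`, `fp`, `fn`, `tn`) or accuracy fractions
#' (`n_diseased`, `n_nondiseased`, `sensitivity`, `specificity`), the latter
#' routed through [reconstruct_table()]. An optional `meta_label` column
#' carries the free-text description.
#'
#' @param path File path, comma- or tab-delimited with a header.
#' @param dialect Optional named character vector mapping canonical column
#'   names (e.g. `"tp"`) to the names used in the file.
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A [corpus()].
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeLines(c("meta_id,study_id,tp,fp,fn,tn",
#'              "m1,s1,9,1,1,9", "m1,s2,45,5,5,45"), p)
#' read_corpus(p)
#' @export
read_corpus <- function(path, dialect = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  counts_mode <- all(.corpus_cols_counts %in% names(raw))
  fracs_mode  <- all(.corpus_cols_fracs %in% names(raw))
  if (!counts_mode && !fracs_mode) {
    stop("format error: need columns ",
         paste(.corpus_cols_counts, collapse = ", "), " or ",
         paste(.corpus_cols_fracs, collapse = ", "),
         "; found: ", paste(names(raw), collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(corpus(list(), provenance = path))
  }
  has_label <- "meta_label" %in% names(raw)
  # data line i of the file is row i + 1 (header)
  tables <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- raw[i, ]
    tab <- tryCatch({
      if (counts_mode) {
        study_table(row$study_id, row$tp, row$fp, row$fn, row$tn)
      } else {
        if (row$sensitivity < 0 || row$sensitivity > 1 ||
            row$specificity < 0 || row$specificity > 1) {
          stop("fractions outside [0, 1]", call. = FALSE)
        }
        reconstruct_table(row$n_diseased, row$n_nondiseased,
                          row$sensitivity, row$specificity,
                          study_id = row$study_id)
      }
    }, error = function(e) {
      stop("validation error at line ", i + 1L, " (study '", row$study_id,
           "'): ", conditionMessage(e), call. = FALSE)
    })
    tables[[i]] <- tab
  }
  meta_ids <- as.character(raw$meta_id)
  order_ids <- unique(meta_ids)
  metas <- lapply(order_ids, function(id) {
    idx <- which(meta_ids == id)
    meta_analysis(id, tables[idx],
                  label = if (has_label) as.character(raw$meta_label[idx[1]]) else "")
  })
  corpus(metas, provenance = path)
}

#' Write a corpus to the canonical delimited format
#'
#' Long-format CSV with columns `meta_id`, `meta_label`, `study_id`, `tp`,
#' `fp`, `fn`, `tn`. `read_corpus(write_corpus(x))` reproduces `x` exactly.
#'
#' @param corpus A [corpus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "corpus"))
  df <- corpus_to_df(corpus)
  tryCatch(write.csv(df, path, row.names = FALSE, quote = TRUE),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Flatten a corpus to a long data.frame
#'
#' @param corpus A [corpus()].
#' @return data.frame with one row per study.
#' @export
corpus_to_df <- function(corpus) {
  if (length(corpus$metas) == 0) {
    return(data.frame(meta_id = character(), meta_label = character(),
                      study_id = character(), tp = integer(), fp = integer(),
                      fn = integer(), tn = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(corpus$metas, function(m) {
    cbind(data.frame(meta_id = m$meta_id, meta_label = m$label,
                     stringsAsFactors = FALSE),
          m$studies, row.names = NULL)
  })) -> df
  rownames(df) <- NULL
  df
}
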