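# Funnel-plot construction for the axis conventions found in published
# diagnostic accuracy reviews: effect (DOR, lnDOR, sensitivity, specificity)
# on x against a size/precision measure on y.

# catalogue of supported (x, y) pairs
.funnel_catalogue <- list(
  ln_dor      = c("se_ln_dor", "inv_var_ln_dor", "inv_sqrt_ess",
                  "sample_size", "se_of_x", "inv_se_of_x"),
  dor         = c("sample_size", "inv_sqrt_ess"),
  sensitivity = c("se_of_x", "inv_se_of_x", "sample_size"),
  specificity = c("se_of_x", "inv_se_of_x", "sample_size")
)

# y axes where small values mean high precision: drawn inverted
.precision_down_axes <- c("se_ln_dor", "inv_sqrt_ess", "se_of_x")

#' Specify funnel-plot axes
#'
#' @param x_axis One of `"ln_dor"`, `"dor"`, `"sensitivity"`,
#'   `"specificity"`.
#' @param y_axis One of `"se_ln_dor"`, `"inv_var_ln_dor"`,
#'   `"inv_sqrt_ess"`, `"sample_size"`, `"se_of_x"`, `"inv_se_of_x"`.
#'   `se_of_x` is the standard error of the x-axis quantity (binomial on the
#'   natural scale for sensitivity/specificity).
#' @param y_inverted Draw the y axis pointing down so the funnel opens
#'   downward; defaults to `TRUE` for SE-like axes.
#' @return A `funnel_spec` object.
#' @export
funnel_spec <- function(x_axis = "ln_dor", y_axis = "inv_sqrt_ess",
                        y_inverted = NULL) {
  if (!x_axis %in% names(.funnel_catalogue) ||
      !y_axis %in% .funnel_catalogue[[x_axis]]) {
    supported <- unlist(lapply(names(.funnel_catalogue), function(x)
      paste0("(", x, ", ", .funnel_catalogue[[x]], ")")))
    stop("unsupported axis pair (", x_axis, ", ", y_axis,
         "); supported: ", paste(supported, collapse = " "), call. = FALSE)
  }
  if (is.null(y_inverted)) y_inverted <- y_axis %in% .precision_down_axes
  structure(list(x_axis = x_axis, y_axis = y_axis,
                 y_inverted = isTRUE(y_inverted)),
            class = "funnel_spec")
}

# per-study x and y values for a spec, from raw counts + effects
.funnel_xy <- function(studies, eff, spec) {
  n1 <- studies$tp + studies$fn
  n2 <- studies$fp + studies$tn
  x <- switch(spec$x_axis,
              ln_dor = eff$ln_dor,
              dor = eff$dor,
              sensitivity = studies$tp / n1,
              specificity = studies$tn / n2)
  se_x <- switch(spec$x_axis,
                 ln_dor = eff$se_ln_dor,
                 dor = eff$dor * eff$se_ln_dor,  # delta method
                 sensitivity = sqrt((studies$tp / n1) * (1 - studies$tp / n1) / n1),
                 specificity = sqrt((studies$tn / n2) * (1 - studies$tn / n2) / n2))
  y <- switch(spec$y_axis,
              se_ln_dor = eff$se_ln_dor,
              inv_var_ln_dor = 1 / eff$var_ln_dor,
              inv_sqrt_ess = eff$inv_sqrt_ess,
              sample_size = eff$n_total,
              se_of_x = se_x,
              inv_se_of_x = 1 / se_x)
  list(x = x, y = y)
}

#' Funnel-plot coordinates for a meta-analysis
#'
#' @param meta A [meta_analysis()].
#' @param spec A [funnel_spec()].
#' @param continuity Continuity constant for zero-cell tables (see
#'   [study_effect()]).
#' @return A `funnel_data` object: `points` is a data.frame
#'   (`study_id`, `x`, `y`), `excluded` lists studies with non-finite
#'   coordinates and the reason, `spec` and `meta_id` identify the plot.
#' @examples
#' m <- meta_analysis("m", data.frame(study_id = "s", tp = 5, fp = 5,
#'                                    fn = 5, tn = 5))
#' funnel_coordinates(m, funnel_spec("ln_dor", "inv_sqrt_ess"))
#' @export
funnel_coordinates <- function(meta, spec = funnel_spec(), continuity = 0.5) {
  stopifnot(inherits(meta, "meta_analysis"), inherits(spec, "funnel_spec"))
  eff <- meta_effects(meta, continuity = continuity)
  xy <- .funnel_xy(meta$studies, eff, spec)
  ok <- is.finite(xy$x) & is.finite(xy$y)
  pts <- data.frame(study_id = meta$studies$study_id[ok],
                    x = xy$x[ok], y = xy$y[ok], stringsAsFactors = FALSE)
  excl <- data.frame(study_id = meta$studies$study_id[!ok],
                     reason = rep("non-finite coordinate", sum(!ok)),
                     stringsAsFactors = FALSE)
  structure(list(meta_id = meta$meta_id, points = pts, excluded = excl,
                 spec = spec),
            class = "funnel_data")
}

#' Render a funnel plot to an image file
#'
#' @param data A `funnel_data` from [funnel_coordinates()].
#' @param path Output path; format chosen from the extension
#'   (`.png`, `.svg`, or `.pdf`).
#' @param pooled Optional pooled log-DOR (or x-scale value) drawn as a
#'   vertical reference line.
#' @return `path`, invisibly.
#' @export
render_funnel <- function(data, path, pooled = NULL) {
  stopifnot(inherits(data, "funnel_data"))
  if (nrow(data$points) == 0) stop("render error: empty funnel data", call. = FALSE)
  .open_device(path)
  on.exit(dev.off())
  ylim <- range(data$points$y)
  if (data$spec$y_inverted) ylim <- rev(ylim)
  plot(data$points$x, data$points$y, ylim = ylim,
       xlab = data$spec$x_axis, ylab = data$spec$y_axis,
       main = paste0("Funnel: ", data$meta_id), pch = 19)
  if (!is.null(pooled)) abline(v = pooled, lty = 2)
  invisible(path)
}

.open_device <- function(path, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png(path, width = width, height = height, units = "in",
                   res = 150, type = "cairo"),
         svg = svg(path, width = width, height = height),
         pdf = pdf(path, width = width, height = height),
         stop("unsupported image format: .", ext, call. = FALSE))
}
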