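#' Feature-extraction configuration
#'
#' Tunable parameters of the measurement stage.
#'
#' @param d co-occurrence offset distance in pixels (default 10).
#' @param angles co-occurrence directions in degrees (default all four).
#' @param entropy_mode `"histogram"` (entropy of the 256-bin grayscale
#'   histogram, a first-order statistic; default) or `"cooccurrence"`
#'   (direction-averaged entropy of the co-occurrence matrix).  Both are
#'   always computed; this switch selects which one populates the
#'   `entropy` field of the feature set.
#' @param n_points number of edge points for longitudinal thickness
#'   (default 100).
#' @param symmetric symmetric co-occurrence counting (default `TRUE`).
#' @return list of class `"qus_config"`.
#' @export
qus_config <- function(d = 10L, angles = c(0, 45, 90, 135),
                       entropy_mode = c("histogram", "cooccurrence"),
                       n_points = 100L, symmetric = TRUE) {
  entropy_mode <- match.arg(entropy_mode)
  stopifnot(d >= 1, n_points >= 2, all(angles %in% c(0, 45, 90, 135)))
  structure(list(d = as.integer(d), angles = angles,
                 entropy_mode = entropy_mode,
                 n_points = as.integer(n_points), symmetric = symmetric),
            class = "qus_config")
}

#' Names of the QUS measurements
#'
#' @param view optionally restrict to the subset defined for one view:
#'   width and area exist only in the transverse view.
#' @return character vector of feature names.
#' @export
qus_feature_names <- function(view = NULL) {
  all <- c("thickness_cm", "width_cm", "area_cm2", "echogenicity",
           "variance", "skewness", "kurtosis", "entropy", "contrast",
           "energy", "homogeneity")
  if (is.null(view)) return(all)
  if (view == "longitudinal") setdiff(all, c("width_cm", "area_cm2")) else all
}

#' Extract the full QUS measurement set from one image + ROI
#'
#' Longitudinal view (band ROI): mean thickness plus the 8 intensity and
#' texture features.  Transverse view (contour ROI): maximum thickness,
#' width and cross-sectional area plus the 8 intensity and texture
#' features.  The ROI's view must match the image's view.
#'
#' @param image a [us_image()].
#' @param roi an `roi` object whose `view` matches the image.
#' @param config a [qus_config()].
#' @return Object of class `"qus_features"`: list with one element per
#'   feature (absent features `NULL`), `undefined` flags, `view`, `id`,
#'   `n_pixels`, and `detail` (per-angle texture values plus both entropy
#'   variants).
#' @export
extract_features <- function(image, roi, config = qus_config()) {
  if (!inherits(image, "us_image")) stop("image must be a us_image")
  if (!inherits(roi, "roi")) stop("roi must be an roi object")
  if (!identical(image$view, roi$view)) {
    stop("view mismatch: image is ", image$view, ", ROI is ", roi$view)
  }
  expected_kind <- if (image$view == "longitudinal") "band" else "contour"
  if (roi$kind != expected_kind) {
    stop(image$view, " view requires a ", expected_kind, " ROI")
  }
  mask <- rasterize_roi(roi, dim(image))
  fo <- first_order_stats(image, mask)
  tx <- texture_features(image, mask, d = config$d, angles = config$angles,
                         symmetric = config$symmetric)
  out <- list(thickness_cm = NULL, width_cm = NULL, area_cm2 = NULL,
              echogenicity = fo$echogenicity, variance = fo$variance,
              skewness = fo$skewness, kurtosis = fo$kurtosis,
              entropy = if (config$entropy_mode == "histogram") fo$entropy
                        else tx$entropy,
              contrast = tx$contrast, energy = tx$energy,
              homogeneity = tx$homogeneity)
  if (image$view == "longitudinal") {
    out$thickness_cm <- longitudinal_thickness(roi, image$calibration,
                                               n_points = config$n_points)
  } else {
    geo <- transverse_geometry(roi, image$calibration)
    out$thickness_cm <- geo$thickness_cm
    out$width_cm <- geo$width_cm
    out$area_cm2 <- geo$area_cm2
  }
  structure(c(out,
              list(undefined = fo$undefined, view = image$view,
                   id = image$id, n_pixels = fo$n_pixels,
                   detail = list(per_angle = tx$per_angle,
                                 entropy_histogram = fo$entropy,
                                 entropy_cooccurrence = tx$entropy))),
            class = "qus_features")
}

#' @export
print.qus_features <- function(x, ...) {
  cat(sprintf("<qus_features '%s'> %s view, %d ROI pixels\n",
              x$id, x$view, x$n_pixels))
  for (f in qus_feature_names(x$view)) {
    v <- x[[f]]
    cat(sprintf("  %-13s %s\n", f,
                if (is.null(v)) "-" else formatC(v, digits = 6, format = "g")))
  }
  invisible(x)
}

#' Flatten one feature set to long-format rows
#'
#' @param features a [extract_features()] result.
#' @param meta named list/vector of design columns to prepend (e.g.
#'   tendon_id, group, evaluator, visit, image).
#' @return data.frame with columns from `meta` plus `view`, `feature`,
#'   `value`, `undefined_flag`.
#' @export
features_to_rows <- function(features, meta = list()) {
  nm <- qus_feature_names(features$view)
  vals <- vapply(nm, function(f) {
    v <- features[[f]]
    if (is.null(v) || is.na(v)) NA_real_ else v
  }, numeric(1))
  # a value is undefined-flagged when the statistic could not be computed
  # (sigma = 0 skewness/kurtosis); absent-by-view features are simply
  # excluded from nm above
  base <- data.frame(view = features$view, feature = nm, value = unname(vals),
                     undefined_flag = unname(is.na(vals)),
                     stringsAsFactors = FALSE, row.names = NULL)
  if (length(meta)) base <- cbind(as.data.frame(meta, stringsAsFactors = FALSE),
                                  base, row.names = NULL)
  base
}
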