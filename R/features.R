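# First-order and geometric QUS measurements.
#
# All grayscale moments use population (1/n) denominators and non-excess
# kurtosis (Gaussian -> 3), exactly as the histogram-statistics formulas
# conventionally used in musculoskeletal QUS define them.

#' First-order grayscale statistics over a masked region
#'
#' Computes echogenicity (mean intensity), variance, skewness, kurtosis and
#' histogram entropy over the pixels selected by `mask`.
#'
#' * variance uses the population denominator (pixel count, no Bessel
#'   correction);
#' * skewness is the third central moment over `sigma^3`;
#' * kurtosis is the fourth central moment over `sigma^4` (non-excess);
#' * entropy is `-sum(q * log2(q))` over the 256-bin normalized grayscale
#'   histogram `q`, with `0 * log(0) == 0`; it is bounded by 8 bits.
#'
#' For a constant region (`sigma == 0`) skewness and kurtosis are undefined
#' and returned as `NA` with their `undefined` flags set; the other
#' statistics remain valid.
#'
#' @param image a [us_image()] or an integer matrix in `[0, 255]`.
#' @param mask logical matrix of the same dimensions; at least one `TRUE`.
#' @return list with `echogenicity`, `variance`, `skewness`, `kurtosis`,
#'   `entropy`, `n_pixels`, and a named logical vector `undefined`.
#' @export
first_order_stats <- function(image, mask) {
  px <- if (inherits(image, "us_image")) image$pixels else image
  if (!identical(dim(px), dim(mask))) stop("image and mask dimensions differ")
  vals <- as.numeric(px[mask])
  n <- length(vals)
  if (n == 0L) stop("empty mask")
  m <- sum(vals) / n
  dev <- vals - m
  v <- sum(dev^2) / n
  if (v > 0) {
    sk <- (sum(dev^3) / n) / v^1.5
    kt <- (sum(dev^4) / n) / v^2
    undef <- c(skewness = FALSE, kurtosis = FALSE)
  } else {
    sk <- NA_real_; kt <- NA_real_
    undef <- c(skewness = TRUE, kurtosis = TRUE)
  }
  q <- tabulate(as.integer(vals) + 1L, nbins = 256L) / n
  q <- q[q > 0]
  ent <- -sum(q * log2(q))
  list(echogenicity = m, variance = v, skewness = sk, kurtosis = kt,
       entropy = ent, n_pixels = n, undefined = undef)
}

#' Mean tendon thickness from a longitudinal band ROI
#'
#' Plots `n_points` points equidistant in x across the common x-interval of
#' the two edges (linear interpolation along each polyline), pairs them by
#' index, and averages the Euclidean distances of the pairs.  Because the
#' paired points share x-coordinates this reduces to the mean vertical
#' separation of the edges.
#'
#' @param roi a band ROI ([roi_band()]).
#' @param calibration a [pixel_calibration()].
#' @param n_points number of edge points (default 100).
#' @return mean thickness in cm.
#' @export
longitudinal_thickness <- function(roi, calibration = pixel_calibration(),
                                   n_points = 100L) {
  if (!inherits(roi, "roi_band")) stop("thickness needs a band ROI")
  if (n_points < 2L) stop("n_points must be >= 2")
  up <- roi$upper_edge; lo <- roi$lower_edge
  x0 <- max(min(up[, 1]), min(lo[, 1]))
  x1 <- min(max(up[, 1]), max(lo[, 1]))
  if (x1 <= x0) stop("band edges span disjoint x-ranges")
  xs <- seq(x0, x1, length.out = n_points)
  yu <- approx(up[, 1], up[, 2], xout = xs)$y
  yl <- approx(lo[, 1], lo[, 2], xout = xs)$y
  d_px <- sqrt((xs - xs)^2 + (yl - yu)^2)
  mean(d_px) * calibration$spacing_mm / 10
}

#' Geometric measurements from a transverse contour ROI
#'
#' Thickness and width are the height and width of the axis-aligned
#' bounding rectangle of the contour ([bounding_rectangle()]); the
#' cross-sectional area is the shoelace polygon area.  All converted to
#' physical units with the pixel calibration.
#'
#' @param roi a contour ROI ([roi_contour()]).
#' @param calibration a [pixel_calibration()].
#' @return list with `thickness_cm`, `width_cm`, `area_cm2`.
#' @export
transverse_geometry <- function(roi, calibration = pixel_calibration()) {
  if (!inherits(roi, "roi_contour")) stop("transverse geometry needs a contour ROI")
  rect <- bounding_rectangle(roi$contour)
  sp <- calibration$spacing_mm
  list(thickness_cm = unname(rect["height_px"]) * sp / 10,
       width_cm = unname(rect["width_px"]) * sp / 10,
       area_cm2 = polygon_area(roi$contour) * sp^2 / 100)
}
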