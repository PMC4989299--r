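# Synthetic B-mode tendon phantom.
#
# A smooth echo map (hyperechoic tendon on a darker background, with the
# alternating fibrillar banding of healthy tendon in the longitudinal view)
# is multiplied by gamma-distributed speckle with unit mean, then clipped
# to 0..255.  Healthy defaults take the asymptomatic group means reported
# for the Achilles tendon (thickness 0.52 cm, echogenicity ~83) and
# pathologic defaults the symptomatic means (0.68 cm, ~79) with a focal
# hypoechoic lesion and attenuated banding -- the sonographic picture of
# midsubstance tendinopathy.

#' Parameters of the synthetic tendon image
#'
#' @param view `"longitudinal"` or `"transverse"`.
#' @param condition `"healthy"` or `"pathologic"`; selects the default
#'   geometry/echotexture unless overridden explicitly.
#' @param thickness_cm tendon thickness (ground truth).  Defaults 0.52
#'   (healthy) / 0.68 (pathologic).
#' @param width_cm tendon width, transverse only.  Defaults 1.30 / 1.37.
#' @param mean_echo mean tendon echo level (0..255).  Defaults 83 / 79.
#' @param band_amplitude amplitude (gray levels) of the fibrillar
#'   striation bands, longitudinal only.  Defaults 30 (healthy) / 10
#'   (pathologic): tendinopathy disrupts the fibrillar pattern.
#' @param band_period_px vertical period of the striation in pixels
#'   (default 8, about 0.6 mm at the default calibration).
#' @param lesion `NULL` or list with `depth` (gray-level drop at the lesion
#'   center) and `radius_frac` (radius as a fraction of tendon thickness).
#'   Default for pathologic: `depth = 35`, `radius_frac = 0.6`.
#' @param speckle_shape gamma shape of the multiplicative speckle (larger =
#'   smoother; default 4, a typical fully developed speckle approximation).
#' @param background_echo echo level of surrounding tissue (default 45).
#' @param rows,cols image size in pixels; defaults accommodate the
#'   geometry at the default calibration.
#' @param calibration a [pixel_calibration()].
#' @return list of class `"tendon_image_params"`.
#' @export
tendon_image_params <- function(view = c("longitudinal", "transverse"),
                                condition = c("healthy", "pathologic"),
                                thickness_cm = NULL, width_cm = NULL,
                                mean_echo = NULL, band_amplitude = NULL,
                                band_period_px = 8, lesion = NULL,
                                speckle_shape = 4, background_echo = 45,
                                rows = NULL, cols = NULL,
                                calibration = pixel_calibration()) {
  view <- match.arg(view)
  condition <- match.arg(condition)
  path <- condition == "pathologic"
  thickness_cm <- thickness_cm %||% if (path) 0.68 else 0.52
  width_cm <- width_cm %||% if (path) 1.37 else 1.30
  mean_echo <- mean_echo %||% if (path) 79 else 83
  band_amplitude <- band_amplitude %||% if (path) 10 else 30
  if (path && is.null(lesion)) lesion <- list(depth = 35, radius_frac = 0.6)
  stopifnot(thickness_cm > 0, width_cm > 0,
            mean_echo > 0, mean_echo < 255, speckle_shape > 0)
  sp <- calibration$spacing_mm
  t_px <- thickness_cm * 10 / sp
  w_px <- width_cm * 10 / sp
  if (is.null(rows)) {
    rows <- ceiling(t_px * 2.2)
  }
  if (is.null(cols)) {
    cols <- if (view == "longitudinal") ceiling(1.4 * 10 / sp)  # > 1 cm span
            else ceiling(w_px * 1.25)
  }
  structure(list(view = view, condition = condition,
                 thickness_cm = thickness_cm, width_cm = width_cm,
                 mean_echo = mean_echo, band_amplitude = band_amplitude,
                 band_period_px = band_period_px, lesion = lesion,
                 speckle_shape = speckle_shape,
                 background_echo = background_echo,
                 rows = as.integer(rows), cols = as.integer(cols),
                 calibration = calibration),
            class = "tendon_image_params")
}

#' Simulate a tendon-like ultrasound image with ground truth
#'
#' Renders the echo map described by `params`, applies unit-mean gamma
#' speckle, clips to 0..255, and returns the image together with the exact
#' ROI tracing of the simulated tendon and the geometric ground truth.
#'
#' Longitudinal: a horizontal band of the ground-truth thickness centered
#' vertically, with sinusoidal fibrillar striation; the returned ROI is the
#' 1-cm-long band between the true edges, centered horizontally.
#' Transverse: an elliptical cross-section; the returned ROI is a 90-vertex
#' polygon on the true ellipse.
#'
#' @param params a [tendon_image_params()].
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return list with `image` ([us_image()]), `roi`, and `truth` (list of
#'   `thickness_cm` and, for transverse, `width_cm` and `area_cm2`).
#' @export
simulate_tendon_image <- function(params = tendon_image_params(),
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- params$calibration$spacing_mm
  nr <- params$rows; nc <- params$cols
  t_px <- params$thickness_cm * 10 / sp
  if (t_px >= nr || (params$view == "transverse" &&
                     params$width_cm * 10 / sp >= nc)) {
    stop("tendon geometry exceeds the image bounds")
  }
  rowc <- matrix(seq_len(nr) - 0.5, nr, nc)          # y of pixel centers
  colc <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
  y_mid <- nr / 2
  echo <- matrix(params$background_echo, nr, nc)

  if (params$view == "longitudinal") {
    y_up <- y_mid - t_px / 2
    y_lo <- y_mid + t_px / 2
    inside <- rowc >= y_up & rowc <= y_lo
    band <- params$mean_echo +
      params$band_amplitude * sin(2 * pi * (rowc - y_up) / params$band_period_px)
    echo[inside] <- band[inside]
    roi_len_px <- 1 * 10 / sp                         # 1-cm ROI length
    x0 <- nc / 2 - roi_len_px / 2
    x1 <- nc / 2 + roi_len_px / 2
    roi <- roi_band(upper_edge = cbind(c(x0, x1), c(y_up, y_up)),
                    lower_edge = cbind(c(x0, x1), c(y_lo, y_lo)))
    truth <- list(thickness_cm = params$thickness_cm)
    cx <- nc / 2; cy <- y_mid
  } else {
    a <- params$width_cm * 10 / sp / 2               # semi-axes in px
    b <- t_px / 2
    cx <- nc / 2; cy <- y_mid
    inside <- ((colc - cx) / a)^2 + ((rowc - cy) / b)^2 <= 1
    echo[inside] <- params$mean_echo
    th <- seq(0, 2 * pi, length.out = 91)[-91]
    roi <- roi_contour(cbind(cx + a * cos(th), cy + b * sin(th)))
    truth <- list(thickness_cm = params$thickness_cm,
                  width_cm = params$width_cm,
                  area_cm2 = pi * a * b * sp^2 / 100)
  }
  if (!is.null(params$lesion)) {
    r_px <- params$lesion$radius_frac * t_px / 2
    blob <- params$lesion$depth *
      exp(-(((colc - cx)^2 + (rowc - cy)^2) / (2 * r_px^2)))
    echo[inside] <- pmax(echo[inside] - blob[inside], 5)
  }
  speckle <- matrix(rgamma(nr * nc, shape = params$speckle_shape,
                           rate = params$speckle_shape), nr, nc)
  px <- pmin(pmax(round(echo * speckle), 0), 255)
  img <- us_image(px, calibration = params$calibration, view = params$view,
                  id = sprintf("sim_%s_%s", params$view, params$condition))
  list(image = img, roi = roi, truth = truth)
}
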