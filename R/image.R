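#' Pixel calibration
#'
#' Physical size of one (square) image pixel.  Either the pixel edge length
#' in mm or the pixel area in mm^2 may be given; the other is derived.  The
#' default pixel area is 0.0057 mm^2, i.e. a pixel edge of
#' `sqrt(0.0057) ~ 0.0755` mm, the micro-pixel size of the ultrasound
#' export this package was designed around.
#'
#' Only square pixels are supported: anisotropic spacing is rejected because
#' every downstream area/thickness conversion assumes a single edge length.
#'
#' @param spacing_mm pixel edge length in mm (> 0), or `NULL`.
#' @param pixel_area_mm2 pixel area in mm^2 (> 0), or `NULL`.
#' @return An object of class `"pixel_calibration"` with fields
#'   `spacing_mm` and `pixel_area_mm2`.
#' @examples
#' pixel_calibration()                      # default 0.0057 mm^2
#' pixel_calibration(spacing_mm = 0.1)
#' @export
pixel_calibration <- function(spacing_mm = NULL, pixel_area_mm2 = NULL) {
  if (is.null(spacing_mm) && is.null(pixel_area_mm2)) {
    pixel_area_mm2 <- 0.0057
  }
  if (!is.null(spacing_mm) && !is.null(pixel_area_mm2)) {
    if (abs(spacing_mm^2 - pixel_area_mm2) > 1e-9 * max(1, pixel_area_mm2)) {
      stop("inconsistent calibration: spacing_mm^2 != pixel_area_mm2 ",
           "(anisotropic pixels are not supported)")
    }
  }
  if (is.null(spacing_mm)) spacing_mm <- sqrt(pixel_area_mm2)
  if (is.null(pixel_area_mm2)) pixel_area_mm2 <- spacing_mm^2
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L ||
      !is.finite(spacing_mm) || spacing_mm <= 0) {
    stop("spacing_mm must be a single positive number")
  }
  structure(list(spacing_mm = spacing_mm, pixel_area_mm2 = pixel_area_mm2),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("<pixel_calibration> %.6f mm/px (%.6f mm^2/px)\n",
              x$spacing_mm, x$pixel_area_mm2))
  invisible(x)
}

#' Ultrasound image container
#'
#' A grayscale ultrasound frame: an M x N matrix of integer intensities in
#' 0..255 (0 = black/anechoic, 255 = white/hyperechoic) with a pixel
#' calibration and a view tag.
#'
#' @param pixels integer/numeric matrix with all values in `[0, 255]`.
#' @param calibration a [pixel_calibration()].
#' @param view `"longitudinal"` or `"transverse"`.
#' @param id opaque label for the frame.
#' @return Object of class `"us_image"`: list with `pixels`, `calibration`,
#'   `view`, `id`.
#' @export
us_image <- function(pixels, calibration = pixel_calibration(),
                     view = c("longitudinal", "transverse"), id = "image") {
  view <- match.arg(view)
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("pixels must be a non-empty matrix")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("pixel intensities must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) {
    stop("pixel intensities must be integers (0..255)")
  }
  if (!inherits(calibration, "pixel_calibration")) {
    stop("calibration must be a pixel_calibration object")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, calibration = calibration,
                 view = view, id = as.character(id)),
            class = "us_image")
}

#' @export
print.us_image <- function(x, ...) {
  cat(sprintf("<us_image '%s'> %d x %d px, %s view, %.4f mm/px\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$view,
              x$calibration$spacing_mm))
  invisible(x)
}

#' @export
dim.us_image <- function(x) dim(x$pixels)

# ---- PGM (portable graymap) -------------------------------------------------
# P2 (ASCII) and P5 (binary) are supported; the text form is what the test
# fixtures and the simulator emit.

#' Read a PGM (P2/P5) grayscale image
#'
#' @param path file path.
#' @return list with `pixels` (integer matrix, row = image row) and `maxval`.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (magic ", magic, ")")
  # read header tokens (width, height, maxval), skipping comments
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") { # comment to end of line
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1L))
        if (ch %in% c("\n", "\r") || ch == "") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  wd <- as.integer(tokens[1]); ht <- as.integer(tokens[2]); mx <- as.integer(tokens[3])
  if (is.na(wd) || is.na(ht) || is.na(mx) || wd < 1L || ht < 1L || mx < 1L) {
    stop("invalid PGM header")
  }
  n <- wd * ht
  if (magic == "P5") {
    bytes <- if (mx > 255L) 2L else 1L
    vals <- readBin(con, "integer", n, size = bytes, signed = FALSE,
                    endian = "big")
  } else {
    txt <- rawToChar(readBin(con, "raw", file.size(path)))
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
    if (length(vals) < n) stop("truncated PGM pixel data")
    vals <- vals[seq_len(n)]
  }
  list(pixels = matrix(vals, nrow = ht, ncol = wd, byrow = TRUE), maxval = mx)
}

#' Write a PGM (P2, plain text) grayscale image
#'
#' @param pixels integer matrix in `[0, 255]`, or a [us_image()].
#' @param path output path.
#' @export
write_pgm <- function(pixels, path) {
  if (inherits(pixels, "us_image")) pixels <- pixels$pixels
  lines <- c("P2", paste(ncol(pixels), nrow(pixels)), "255",
             apply(pixels, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

# ---- Python bridge for PNG / JPEG / DICOM ----------------------------------

.python_bin <- function() {
  Sys.which("python")
}

.img_bridge <- function(args) {
  script <- system.file("python", "imgbridge.py", package = "tendonqus")
  if (script == "") stop("imgbridge.py not found; package not installed?")
  py <- .python_bin()
  if (py == "") stop("python interpreter not found on PATH; ",
                     "PNG/JPEG/DICOM input requires it (PGM does not)")
  out <- suppressWarnings(system2(py, c(shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0L) {
    stop("image bridge failed: ", paste(out, collapse = " "))
  }
  out
}

#' Load an ultrasound image from disk
#'
#' Reads a grayscale frame and attaches a pixel calibration and view tag.
#' PGM (P2/P5) is read natively; PNG and JPEG are decoded through the
#' Python Pillow library; files ending in `.dcm` are read as DICOM through
#' pydicom (the modality must be `US`; window/level is ignored).
#'
#' Intensities must be 8-bit.  A deeper image (e.g. 16-bit) is rejected
#' unless `rescale = TRUE`, in which case it is min-max rescaled to 0..255.
#' A color image is accepted only when all channels are identical, or when
#' `collapse = TRUE` (channel mean, rounded).
#'
#' @param path image file (`.pgm`, `.png`, `.jpg`, `.jpeg`, `.dcm`).
#' @param calibration a [pixel_calibration()].
#' @param view `"longitudinal"` or `"transverse"`.
#' @param collapse collapse unequal RGB channels by averaging.
#' @param rescale min-max rescale non-8-bit data to 0..255.
#' @param id frame label; defaults to the file name.
#' @return A [us_image()].
#' @export
load_image <- function(path, calibration = pixel_calibration(),
                       view = c("longitudinal", "transverse"),
                       collapse = FALSE, rescale = FALSE,
                       id = basename(path)) {
  view <- match.arg(view)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pgm", "pnm")) {
    dat <- read_pgm(path)
  } else if (ext %in% c("png", "jpg", "jpeg", "dcm")) {
    tmp <- tempfile(fileext = ".pgm")
    on.exit(unlink(tmp), add = TRUE)
    mode <- if (ext == "dcm") "dicom" else "decode"
    .img_bridge(c(mode, shQuote(path), shQuote(tmp),
                  if (collapse) "--collapse"))
    dat <- read_pgm(tmp)
  } else {
    stop("unsupported image format: .", ext)
  }
  px <- dat$pixels
  if (dat$maxval > 255L) {
    if (!rescale) {
      stop("image bit depth exceeds 8 bits; pass rescale = TRUE to min-max ",
           "rescale to 0..255")
    }
    rng <- range(px)
    px <- if (rng[2] > rng[1]) {
      as.integer(round((px - rng[1]) / (rng[2] - rng[1]) * 255))
    } else matrix(0L, nrow(px), ncol(px))
    dim(px) <- dim(dat$pixels)
  }
  us_image(px, calibration = calibration, view = view, id = id)
}

#' Write an image as PNG through the Python bridge
#'
#' @param pixels integer matrix or [us_image()].
#' @param path output `.png` path.
#' @export
write_png <- function(pixels, path) {
  tmp <- tempfile(fileext = ".pgm")
  on.exit(unlink(tmp))
  write_pgm(pixels, tmp)
  .img_bridge(c("encode", shQuote(tmp), shQuote(path)))
  invisible(path)
}
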