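# Gray-level co-occurrence texture features.
#
# The GLCM is built over the full 256-level grayscale (no quantization).
# The four standard directions are mapped to integer (row, col) offsets:
#   0 deg   -> ( 0, +d)
#   45 deg  -> (-d, +d)
#   90 deg  -> (-d,  0)
#   135 deg -> (-d, -d)
# Diagonal offsets step d pixels in each axis (Chebyshev distance d), so
# results are bit-for-bit reproducible without rounding conventions.
# Symmetric counting (each ordered pair plus its reverse) is the default,
# which makes 0/180 and 45/225 degrees equivalent.

.angle_offset <- function(angle, d) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135 (degrees)"))
}

#' Gray-level co-occurrence matrix over a masked region
#'
#' Counts all ordered pixel pairs `(p1, p2 = p1 + offset)` with both pixels
#' inside the mask, at offset distance `d` and the given direction, then
#' normalizes the counts to probabilities.  With `symmetric = TRUE`
#' (default) each pair is also counted in the reversed order, making the
#' matrix symmetric.
#'
#' @param image a [us_image()] or integer matrix in `[0, 255]`.
#' @param mask logical matrix of the same dimensions.
#' @param d offset distance in pixels (>= 1); default 10.
#' @param angle direction in degrees: 0, 45, 90 or 135.
#' @param symmetric also count reversed pairs (default `TRUE`).
#' @return Object of class `"glcm"`: list with `p` (256 x 256 probability
#'   matrix, rows/cols indexed by gray level 0..255), `d`, `angle`,
#'   `n_pairs` (ordered pairs counted, including reverses).
#' @export
cooccurrence_matrix <- function(image, mask, d = 10L, angle = 0,
                                symmetric = TRUE) {
  px <- if (inherits(image, "us_image")) image$pixels else image
  if (!identical(dim(px), dim(mask))) stop("image and mask dimensions differ")
  if (!any(mask)) stop("empty mask")
  d <- as.integer(d)
  if (d < 1L) stop("offset distance d must be >= 1")
  off <- .angle_offset(angle, d)
  nr <- nrow(px); nc <- ncol(px)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  if (length(r1) == 0L || length(c1) == 0L ||
      r1[1] > r1[length(r1)] || c1[1] > c1[length(c1)]) {
    stop("no co-occurring pixel pair exists for d = ", d,
         ", angle = ", angle)
  }
  sub1 <- mask[r1, c1, drop = FALSE] & mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(sub1)) {
    stop("no co-occurring pixel pair exists for d = ", d, ", angle = ", angle)
  }
  i <- as.integer(px[r1, c1, drop = FALSE][sub1])
  j <- as.integer(px[r1 + off[1], c1 + off[2], drop = FALSE][sub1])
  counts <- tabulate(i * 256L + j + 1L, nbins = 256L * 256L)
  if (symmetric) counts <- counts + tabulate(j * 256L + i + 1L, nbins = 256L * 256L)
  n_pairs <- sum(counts)
  p <- matrix(counts / n_pairs, 256L, 256L, byrow = TRUE,
              dimnames = list(0:255, 0:255))
  structure(list(p = p, d = d, angle = angle, n_pairs = n_pairs,
                 symmetric = symmetric),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("<glcm> d = %d, angle = %s deg, %d pairs, %d nonzero cells\n",
              x$d, format(x$angle), x$n_pairs, sum(x$p > 0)))
  invisible(x)
}

#' Texture features of one co-occurrence matrix
#'
#' Evaluates, over the nonzero cells of `p(i, j)`:
#' contrast `sum(|i - j|^2 p)`, energy `sum(p^2)`, homogeneity
#' `sum(p / (1 + (i - j)^2))` and entropy `-sum(p log2 p)`.
#'
#' @param glcm a [cooccurrence_matrix()] result.
#' @return named numeric vector `contrast`, `energy`, `homogeneity`,
#'   `entropy`.
#' @export
glcm_features <- function(glcm) {
  nz <- which(glcm$p > 0)
  p <- glcm$p[nz]
  ij <- arrayInd(nz, dim(glcm$p))
  dlev <- (ij[, 1] - ij[, 2])^2          # (i - j)^2 in gray-level units
  c(contrast = sum(dlev * p),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + dlev)),
    entropy = -sum(p * log2(p)))
}

#' Direction-averaged co-occurrence texture features
#'
#' Computes the co-occurrence matrix for each requested direction and
#' returns the arithmetic mean of contrast, energy, homogeneity and
#' co-occurrence entropy across directions.  Per-direction values are kept
#' in the `per_angle` element.  An error in any direction (e.g. the mask is
#' too small for the offset) propagates.
#'
#' @inheritParams cooccurrence_matrix
#' @param angles directions in degrees (default all four).
#' @return list with `contrast`, `energy`, `homogeneity`, `entropy`
#'   (direction means) and `per_angle` (matrix, one row per direction).
#' @export
texture_features <- function(image, mask, d = 10L,
                             angles = c(0, 45, 90, 135), symmetric = TRUE) {
  per <- t(vapply(angles, function(a) {
    glcm_features(cooccurrence_matrix(image, mask, d = d, angle = a,
                                      symmetric = symmetric))
  }, numeric(4)))
  rownames(per) <- paste0(angles, "deg")
  m <- colMeans(per)
  list(contrast = unname(m["contrast"]), energy = unname(m["energy"]),
       homogeneity = unname(m["homogeneity"]), entropy = unname(m["entropy"]),
       per_angle = per)
}
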