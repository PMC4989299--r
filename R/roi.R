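# Regions of interest.
#
# Two tracing styles are supported, matching how tendon ROIs are drawn in
# practice: a closed contour polygon around the whole cross-section
# (transverse view) and a "band" delimited by an upper and a lower edge
# polyline along the tendon axis (longitudinal view).  Coordinates are
# pixel units, origin at the top-left image corner, x = column index,
# y = row index (larger y = deeper); pixel (r, c) has center
# (c + 0.5, r + 0.5), 0-based r and c.

.as_vertex_matrix <- function(v, what) {
  if (is.list(v)) v <- do.call(rbind, lapply(v, as.numeric))
  v <- as.matrix(v)
  if (ncol(v) != 2L || anyNA(v) || !is.numeric(v)) {
    stop(what, " must be an n x 2 numeric matrix of (x, y) vertices")
  }
  storage.mode(v) <- "double"
  colnames(v) <- c("x", "y")
  v
}

# strict segment-intersection test for the simple-polygon check;
# shared endpoints between adjacent edges are skipped by the caller.
.segments_cross <- function(p1, p2, q1, q2) {
  orient <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- orient(q1, q2, p1); d2 <- orient(q1, q2, p2)
  d3 <- orient(p1, p2, q1); d4 <- orient(p1, p2, q2)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.is_simple_polygon <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L)) {
    for (j in seq((i + 2L), n)) {
      if (i == 1L && j == n) next      # adjacent through the closing edge
      if (.segments_cross(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Contour region of interest
#'
#' A closed polygon traced around the tendon outline (transverse view).
#'
#' @param vertices n x 2 matrix (or list of pairs) of (x, y) pixel
#'   coordinates, at least 3 vertices, simple (non-self-intersecting),
#'   non-zero area.  The polygon is implicitly closed.
#' @param view the view the tracing applies to (default `"transverse"`).
#' @return Object of class `c("roi_contour", "roi")`.
#' @export
roi_contour <- function(vertices, view = "transverse") {
  v <- .as_vertex_matrix(vertices, "contour")
  # drop an explicitly repeated closing vertex
  if (nrow(v) > 1L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) stop("degenerate ROI: contour needs >= 3 vertices")
  if (!.is_simple_polygon(v)) stop("degenerate ROI: self-intersecting contour")
  if (polygon_area(v) == 0) stop("degenerate ROI: zero-area contour")
  structure(list(kind = "contour", contour = v, view = view),
            class = c("roi_contour", "roi"))
}

.check_edge <- function(e, what) {
  if (nrow(e) < 2L) stop(what, " edge needs >= 2 vertices")
  if (all(diff(e[, 1]) < 0)) e <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  if (any(diff(e[, 1]) <= 0)) {
    stop(what, " edge must be x-monotone (strictly increasing x)")
  }
  e
}

#' Band region of interest
#'
#' The region between an upper and a lower edge polyline (longitudinal
#' view).  Both edges must be x-monotone and the lower edge must lie
#' strictly below (larger y than) the upper edge everywhere on their
#' common x-interval.
#'
#' @param upper_edge,lower_edge n x 2 matrices of (x, y) pixel coordinates.
#' @param view the view the tracing applies to (default `"longitudinal"`).
#' @return Object of class `c("roi_band", "roi")`.
#' @export
roi_band <- function(upper_edge, lower_edge, view = "longitudinal") {
  up <- .check_edge(.as_vertex_matrix(upper_edge, "upper"), "upper")
  lo <- .check_edge(.as_vertex_matrix(lower_edge, "lower"), "lower")
  x0 <- max(min(up[, 1]), min(lo[, 1]))
  x1 <- min(max(up[, 1]), max(lo[, 1]))
  if (x1 <= x0) stop("band edges span disjoint x-ranges")
  xs <- sort(unique(c(up[, 1], lo[, 1])))
  xs <- xs[xs >= x0 & xs <= x1]
  xs <- unique(c(x0, xs, x1, (x0 + x1) / 2))
  yu <- approx(up[, 1], up[, 2], xout = xs)$y
  yl <- approx(lo[, 1], lo[, 2], xout = xs)$y
  if (any(yl <= yu)) {
    stop("degenerate ROI: lower edge must lie strictly below the upper edge")
  }
  structure(list(kind = "band", upper_edge = up, lower_edge = lo, view = view),
            class = c("roi_band", "roi"))
}

#' @export
print.roi <- function(x, ...) {
  if (x$kind == "contour") {
    cat(sprintf("<roi contour> %d vertices, %s view, area %.1f px^2\n",
                nrow(x$contour), x$view, polygon_area(x$contour)))
  } else {
    cat(sprintf("<roi band> upper %d / lower %d vertices, %s view\n",
                nrow(x$upper_edge), nrow(x$lower_edge), x$view))
  }
  invisible(x)
}

#' Read / write an ROI tracing as JSON
#'
#' The JSON schema has fields `kind` (`"contour"` or `"band"`), `view`,
#' and either `contour` or `upper_edge` + `lower_edge`, each an array of
#' `[x, y]` pixel-coordinate pairs (0-based).
#'
#' @param path JSON file path.
#' @return [read_roi()] returns an `roi` object; [write_roi()] returns the
#'   path, invisibly.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  js <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (is.null(js$kind)) stop("ROI JSON missing 'kind'")
  if (js$kind == "contour") {
    roi_contour(js$contour, view = js$view %||% "transverse")
  } else if (js$kind == "band") {
    roi_band(js$upper_edge, js$lower_edge, view = js$view %||% "longitudinal")
  } else stop("unknown ROI kind: ", js$kind)
}

#' @param roi an `roi` object.
#' @rdname read_roi
#' @export
write_roi <- function(roi, path) {
  js <- if (roi$kind == "contour") {
    list(kind = "contour", view = roi$view, contour = unname(roi$contour))
  } else {
    list(kind = "band", view = roi$view,
         upper_edge = unname(roi$upper_edge),
         lower_edge = unname(roi$lower_edge))
  }
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shoelace polygon area
#'
#' Absolute area of a simple polygon in squared pixel units, independent of
#' traversal direction.
#'
#' @param vertices n x 2 matrix of (x, y) vertices (implicitly closed).
#' @return area in px^2.
#' @export
polygon_area <- function(vertices) {
  v <- .as_vertex_matrix(vertices, "polygon")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Axis-aligned bounding rectangle of a contour
#'
#' Width and height (in pixels) of the minimal axis-aligned rectangle
#' enclosing the vertices.  The rectangle height is the tendon's maximum
#' thickness and its width the tendon's width in the transverse view.
#'
#' @param vertices n x 2 matrix (or list) of (x, y) vertices, n >= 1.
#' @return named numeric vector `c(width_px = , height_px = )`.
#' @export
bounding_rectangle <- function(vertices) {
  v <- .as_vertex_matrix(vertices, "contour")
  if (nrow(v) < 1L) stop("empty vertex list")
  w <- max(v[, 1]) - min(v[, 1])
  h <- max(v[, 2]) - min(v[, 2])
  if (w == 0 && h == 0) warning("degenerate ROI: all vertices coincide")
  c(width_px = w, height_px = h)
}

# point-on-segment test, used for the boundary-inclusion rule
.on_boundary <- function(px, py, v, eps = 1e-9) {
  n <- nrow(v)
  on <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    cross <- abs((px - x1) * (y2 - y1) - (py - y1) * (x2 - x1))
    len2 <- (x2 - x1)^2 + (y2 - y1)^2
    within <- (px - x1) * (px - x2) + (py - y1) * (py - y2) <= eps
    on <- on | (cross <= eps * max(1, sqrt(len2)) & within)
  }
  on
}

#' Rasterize a region of interest to a pixel mask
#'
#' A pixel belongs to the mask when its center lies inside the region:
#' even-odd (ray-crossing) rule for contours, vertical containment between
#' the interpolated edges for bands.  Pixel centers exactly on the region
#' boundary are included.  The result is deterministic: identical inputs
#' give bit-identical masks.
#'
#' @param roi an `roi` object.
#' @param image_dims `c(rows, cols)` of the target image, or a [us_image()].
#' @return logical matrix of the given dimensions (class `"pixel_mask"`).
#' @export
rasterize_roi <- function(roi, image_dims) {
  if (inherits(image_dims, "us_image")) image_dims <- dim(image_dims)
  nr <- as.integer(image_dims[1]); nc <- as.integer(image_dims[2])
  mask <- matrix(FALSE, nr, nc)
  if (roi$kind == "contour") {
    v <- roi$contour
    if (any(v[, 1] < 0) || any(v[, 2] < 0) ||
        any(v[, 1] > nc) || any(v[, 2] > nr)) {
      stop("ROI vertices fall outside the image bounds")
    }
    cmin <- max(1L, floor(min(v[, 1]) - 0.5) + 1L)
    cmax <- min(nc, ceiling(max(v[, 1]) + 0.5))
    rmin <- max(1L, floor(min(v[, 2]) - 0.5) + 1L)
    rmax <- min(nr, ceiling(max(v[, 2]) + 0.5))
    if (cmax < cmin || rmax < rmin) return(.as_mask(mask))
    cols <- cmin:cmax; rows <- rmin:rmax
    px <- rep(cols - 0.5, each = length(rows))
    py <- rep(rows - 0.5, times = length(cols))
    inside <- rep(FALSE, length(px))
    n <- nrow(v)
    for (i in seq_len(n)) {                    # even-odd ray cast toward +x
      j <- if (i == n) 1L else i + 1L
      x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
      crosses <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      crosses[is.na(crosses)] <- FALSE
      inside <- xor(inside, crosses)
    }
    inside <- inside | .on_boundary(px, py, v)
    mask[cbind(rep(rows, times = length(cols)),
               rep(cols, each = length(rows)))] <- inside
  } else {
    up <- roi$upper_edge; lo <- roi$lower_edge
    x0 <- max(min(up[, 1]), min(lo[, 1]))
    x1 <- min(max(up[, 1]), max(lo[, 1]))
    cols <- which(seq_len(nc) - 0.5 >= x0 & seq_len(nc) - 0.5 <= x1)
    for (cc in cols) {
      xc <- cc - 0.5
      yu <- approx(up[, 1], up[, 2], xout = xc)$y
      yl <- approx(lo[, 1], lo[, 2], xout = xc)$y
      rows <- which(seq_len(nr) - 0.5 >= yu & seq_len(nr) - 0.5 <= yl)
      mask[rows, cc] <- TRUE
    }
  }
  if (!any(mask)) stop("ROI rasterizes to an empty mask")
  .as_mask(mask)
}

.as_mask <- function(m) {
  class(m) <- c("pixel_mask", class(m))
  m
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d, %d pixels set\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}
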