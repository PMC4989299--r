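# Image loading, calibration, ROI parsing and rasterization.

test_that("default calibration matches the 0.0057 mm^2 micro-pixel", {
  cal <- pixel_calibration()
  expect_equal(cal$pixel_area_mm2, 0.0057)
  expect_equal(cal$spacing_mm, sqrt(0.0057))
  expect_error(pixel_calibration(spacing_mm = -1), "positive")
  expect_error(pixel_calibration(spacing_mm = 0.1, pixel_area_mm2 = 0.02),
               "anisotropic")
})

test_that("PGM round-trip and load_image attach calibration and view", {
  px <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  f <- tempfile(fileext = ".pgm")
  write_pgm(px, f)
  img <- load_image(f, view = "transverse")
  expect_s3_class(img, "us_image")
  expect_identical(dim(img), c(64L, 64L))
  expect_equal(img$pixels, matrix(as.integer(px), 64, 64))
  expect_equal(img$calibration$pixel_area_mm2, 0.0057)
  expect_identical(img$view, "transverse")
})

test_that("PNG decoding through the bridge matches the PGM source", {
  px <- matrix(sample(0:255, 30 * 40, replace = TRUE), 30, 40)
  pgm <- tempfile(fileext = ".pgm"); png <- tempfile(fileext = ".png")
  write_pgm(px, pgm)
  write_png(px, png)
  img <- load_image(png, view = "longitudinal")
  expect_equal(img$pixels, matrix(as.integer(px), 30, 40))
})

test_that("RGB handling: equal channels pass, unequal need collapse", {
  # build RGB PNGs via python (the same interpreter the bridge uses)
  py <- Sys.which("python")
  dir <- tempfile(); dir.create(dir)
  script <- sprintf('
import numpy as np
from PIL import Image
g = np.arange(100, dtype=np.uint8).reshape(10, 10)
Image.fromarray(np.stack([g, g, g], axis=2)).save(r"%s/eq.png")
r = g.copy(); r[0, 0] = 200
Image.fromarray(np.stack([r, g, g], axis=2)).save(r"%s/neq.png")
Image.fromarray((g.astype(np.uint16) * 256)).save(r"%s/deep.png")
', dir, dir, dir)
  writeLines(script, file.path(dir, "mk.py"))
  expect_equal(system2(py, file.path(dir, "mk.py")), 0L)

  eq <- load_image(file.path(dir, "eq.png"), view = "transverse")
  expect_equal(eq$pixels[1, ], 0:9)
  expect_error(load_image(file.path(dir, "neq.png"), view = "transverse"),
               "channels")
  neq <- load_image(file.path(dir, "neq.png"), view = "transverse",
                    collapse = TRUE)
  expect_equal(neq$pixels[1, 1], as.integer(round((200 + 0 + 0) / 3)))
  # 16-bit: rejected without the rescale flag, min-max rescaled with it
  expect_error(load_image(file.path(dir, "deep.png"), view = "transverse"),
               "bit depth")
  deep <- load_image(file.path(dir, "deep.png"), view = "transverse",
                     rescale = TRUE)
  expect_equal(range(deep$pixels), c(0L, 255L))
})

test_that("ROI JSON round-trips both kinds", {
  r1 <- roi_contour(rbind(c(1, 1), c(20, 2), c(18, 15), c(2, 14)))
  r2 <- roi_band(rbind(c(0, 5), c(30, 6)), rbind(c(0, 15), c(30, 17)))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_roi(r1, f1); write_roi(r2, f2)
  b1 <- read_roi(f1); b2 <- read_roi(f2)
  expect_equal(unname(b1$contour), unname(r1$contour))
  expect_equal(unname(b2$upper_edge), unname(r2$upper_edge))
  expect_identical(b2$kind, "band")
})

test_that("degenerate ROIs are rejected", {
  expect_error(roi_contour(rbind(c(0, 0), c(1, 1))), ">= 3")
  expect_error(roi_contour(rbind(c(0, 0), c(5, 5), c(10, 10))), "zero-area")
  expect_error(roi_contour(rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))),
               "self-intersect")
  expect_error(roi_band(rbind(c(0, 2), c(10, 2)), rbind(c(0, 2), c(10, 2))),
               "strictly below")
  expect_error(roi_band(rbind(c(0, 2), c(5, 2)), rbind(c(6, 5), c(10, 5))),
               "disjoint")
})

test_that("rasterization follows the pixel-center rule", {
  sq <- roi_contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  m <- rasterize_roi(sq, c(20, 20))
  expect_equal(sum(m), 100L)              # centers 0.5 .. 9.5
  expect_true(all(which(m, arr.ind = TRUE) <= 10))

  tri <- roi_contour(rbind(c(0, 0), c(4, 0), c(0, 4)))
  expect_equal(polygon_area(tri$contour), 8)
  expect_lte(abs(sum(rasterize_roi(tri, c(10, 10))) - 8), 4)

  # against the independent point-in-polygon oracle on an irregular polygon
  set.seed(42)
  ang <- sort(runif(12, 0, 2 * pi))
  poly <- cbind(15 + (6 + runif(12, 0, 5)) * cos(ang),
                15 + (6 + runif(12, 0, 5)) * sin(ang))
  roi <- roi_contour(poly)
  m <- rasterize_roi(roi, c(30, 30))
  for (r in 1:30) for (cc in 1:30) {
    expect_identical(unclass(m)[r, cc],
                     oracle_point_in_polygon(cc - 0.5, r - 0.5, poly),
                     label = sprintf("pixel (%d,%d)", r, cc))
  }
})

test_that("band rasterization fills between interpolated edges", {
  roi <- roi_band(rbind(c(0, 3), c(20, 3)), rbind(c(0, 9), c(20, 9)))
  m <- rasterize_roi(roi, c(15, 20))
  # rows with center y in [3, 9]: rows 4..9 (centers 3.5..8.5); all 20 cols
  expect_equal(sum(m), 6L * 20L)
  expect_true(all(m[4:9, ]))
})

test_that("mask area converges to polygon area for large convex ROIs", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  poly <- cbind(40 + 30 * cos(th), 35 + 25 * sin(th))
  roi <- roi_contour(poly)
  m <- rasterize_roi(roi, c(80, 80))
  expect_gt(sum(m), 500)
  expect_lt(abs(sum(m) - polygon_area(poly)) / polygon_area(poly), 0.02)
})

test_that("rasterization is deterministic", {
  roi <- roi_contour(rbind(c(2.2, 1.7), c(17.3, 3.1), c(14.8, 16.4),
                           c(4.4, 13.2)))
  expect_identical(rasterize_roi(roi, c(20, 20)), rasterize_roi(roi, c(20, 20)))
})

test_that("bounding_rectangle is exact and order-invariant", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- cbind(25 + 20 * cos(th), 12 + 5 * sin(th))
  expect_equal(unname(bounding_rectangle(ell)), c(40, 10))
  expect_warning(bounding_rectangle(rbind(c(3, 3), c(3, 3))), "degenerate")

  set.seed(7)
  poly <- cbind(runif(50, 0, 100), runif(50, 0, 60))
  bb <- bounding_rectangle(poly)
  expect_equal(unname(bb),
               c(max(poly[, 1]) - min(poly[, 1]),
                 max(poly[, 2]) - min(poly[, 2])))
  shuffled <- poly[sample(50), ]
  expect_equal(bounding_rectangle(shuffled), bb)
  expect_equal(bounding_rectangle(rbind(poly, poly)), bb)  # duplication
})
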