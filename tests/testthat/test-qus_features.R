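# First-order statistics, geometry and co-occurrence texture features.

test_that("first-order closed forms: constant and two-point regions", {
  m <- matrix(TRUE, 10, 10)
  fo <- first_order_stats(matrix(100L, 10, 10), m)
  expect_equal(fo$echogenicity, 100)
  expect_equal(fo$variance, 0)
  expect_true(is.na(fo$skewness) && is.na(fo$kurtosis))
  expect_true(all(fo$undefined))
  expect_equal(fo$entropy, 0)

  two <- matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10)
  fo2 <- first_order_stats(two, m)
  expect_equal(fo2$echogenicity, 127.5)
  expect_equal(fo2$variance, 16256.25)
  expect_equal(fo2$skewness, 0)
  expect_equal(fo2$kurtosis, 1)
  expect_equal(fo2$entropy, 1)
  expect_false(any(fo2$undefined))
})

test_that("first-order stats equal the naive moment oracle", {
  set.seed(11)
  for (k in 1:100) {
    im <- random_image_mask(sample(5:50, 1), sample(5:50, 1))
    fo <- first_order_stats(im$px, im$mask)
    or <- oracle_moments(as.integer(im$px[im$mask]))
    expect_equal(fo$echogenicity, or$mean, tolerance = 1e-12)
    expect_equal(fo$variance, or$variance, tolerance = 1e-12)
    if (!is.na(or$skewness)) {
      expect_equal(fo$skewness, or$skewness, tolerance = 1e-9)
      expect_equal(fo$kurtosis, or$kurtosis, tolerance = 1e-9)
    }
    expect_equal(fo$entropy, or$entropy, tolerance = 1e-12)
  }
})

test_that("intensity shift moves the mean only", {
  set.seed(12)
  im <- random_image_mask(30, 30, levels = 40:200)
  a <- first_order_stats(im$px, im$mask)
  b <- first_order_stats(im$px + 30L, im$mask)
  expect_equal(b$echogenicity, a$echogenicity + 30)
  expect_equal(b$variance, a$variance)
  expect_equal(b$skewness, a$skewness)
  expect_equal(b$kurtosis, a$kurtosis)
  ta <- texture_features(im$px, im$mask, d = 3)
  tb <- texture_features(im$px + 30L, im$mask, d = 3)
  expect_equal(tb$contrast, ta$contrast)
  expect_equal(tb$energy, ta$energy)
  expect_equal(tb$homogeneity, ta$homogeneity)
})

test_that("longitudinal thickness: constant, wedge and error cases", {
  cal <- pixel_calibration(spacing_mm = 0.1)
  flat <- roi_band(rbind(c(0, 10), c(50, 10)), rbind(c(0, 30), c(50, 30)))
  expect_equal(longitudinal_thickness(flat, cal), 0.20)

  # wedge: upper y=10, lower edge varying linearly 20 -> 40 px; the
  # brute-force average of the 100 interpolated pair distances is 20 px
  # (mean of 10..30), i.e. 0.20 cm
  wedge <- roi_band(rbind(c(0, 10), c(50, 10)), rbind(c(0, 20), c(50, 40)))
  xs <- seq(0, 50, length.out = 100)
  dists <- (20 + (40 - 20) * xs / 50) - 10
  expect_equal(longitudinal_thickness(wedge, cal),
               mean(dists) * 0.1 / 10, tolerance = 1e-9)
  expect_equal(longitudinal_thickness(wedge, cal), 0.20, tolerance = 1e-6)
  expect_error(longitudinal_thickness(flat, cal, n_points = 1), ">= 2|replace")
})

test_that("transverse geometry: rectangle, ellipse, orientation", {
  cal <- pixel_calibration(spacing_mm = 0.1)
  rect <- roi_contour(rbind(c(0, 0), c(100, 0), c(100, 40), c(0, 40)))
  g <- transverse_geometry(rect, cal)
  expect_equal(g$width_cm, 1.00)
  expect_equal(g$thickness_cm, 0.40)
  expect_equal(g$area_cm2, 0.40)

  th <- seq(0, 2 * pi, length.out = 361)[-361]
  ell <- roi_contour(cbind(70 + 60 * cos(th), 30 + 25 * sin(th)))
  ge <- transverse_geometry(ell, cal)
  expect_equal(ge$area_cm2, pi * 60 * 25 * 0.01 / 100, tolerance = 1e-3)
  expect_equal(ge$area_cm2, 0.4712, tolerance = 1e-3)

  ccw <- roi_contour(cbind(70 + 60 * cos(th), 30 + 25 * sin(th))[rev(seq_along(th)), ])
  expect_equal(transverse_geometry(ccw, cal)$area_cm2, ge$area_cm2,
               tolerance = 1e-9)
})

test_that("co-occurrence closed forms", {
  # 2x2 constant zeros, d=1, 0 deg
  g <- cooccurrence_matrix(matrix(0L, 2, 2), matrix(TRUE, 2, 2),
                           d = 1, angle = 0)
  expect_equal(g$p["0", "0"], 1)
  expect_equal(g$n_pairs, 4L)            # 2 ordered pairs + reverses
  f <- glcm_features(g)
  expect_equal(unname(f), c(0, 1, 1, 0))

  # 1x4 alternating row
  g2 <- cooccurrence_matrix(matrix(c(0L, 255L, 0L, 255L), 1, 4),
                            matrix(TRUE, 1, 4), d = 1, angle = 0)
  expect_equal(g2$p["0", "255"], 0.5)
  expect_equal(g2$p["255", "0"], 0.5)
  f2 <- glcm_features(g2)
  expect_equal(f2[["contrast"]], 65025)
  expect_equal(f2[["energy"]], 0.5)
  expect_equal(f2[["homogeneity"]], 1 / (1 + 65025), tolerance = 1e-9)
  expect_equal(f2[["entropy"]], 1)

  # masked-out middle pixel leaves no pair
  mask <- matrix(c(TRUE, FALSE, TRUE), 1, 3)
  expect_error(cooccurrence_matrix(matrix(0L, 1, 3), mask, d = 1, angle = 0),
               "no co-occurring")
  # mask smaller than the offset
  expect_error(cooccurrence_matrix(matrix(0L, 3, 3), matrix(TRUE, 3, 3),
                                   d = 10, angle = 0), "no co-occurring")
})

test_that("GLCM features match exhaustive pair enumeration", {
  set.seed(13)
  for (k in 1:12) {
    nr <- sample(4:12, 1); nc <- sample(4:12, 1)
    im <- random_image_mask(nr, nc, levels = 0:7)
    ds <- c(1, if (nr > 10 && nc > 10) 10)
    for (d in ds) for (a in c(0, 45, 90, 135)) {
      or <- oracle_glcm(im$px, im$mask, d, a)
      if (is.null(or)) {
        expect_error(cooccurrence_matrix(im$px, im$mask, d = d, angle = a))
      } else {
        got <- glcm_features(cooccurrence_matrix(im$px, im$mask,
                                                 d = d, angle = a))
        expect_equal(got, or, tolerance = 1e-12)
      }
    }
  }
})

test_that("texture invariant bounds hold on random images", {
  set.seed(14)
  for (k in 1:20) {
    im <- random_image_mask(15, 15)
    tx <- texture_features(im$px, im$mask, d = 2)
    expect_gte(tx$energy, 0); expect_lte(tx$energy, 1)
    expect_gt(tx$homogeneity, 0); expect_lte(tx$homogeneity, 1)
    expect_gte(tx$contrast, 0); expect_lte(tx$contrast, 255^2)
    expect_gte(tx$entropy, 0)
  }
  # equality cases
  g <- cooccurrence_matrix(matrix(7L, 4, 4), matrix(TRUE, 4, 4),
                           d = 1, angle = 90)
  f <- glcm_features(g)
  expect_equal(f[["energy"]], 1)        # single nonzero cell
  expect_equal(f[["homogeneity"]], 1)   # all mass on the diagonal
})

test_that("extract_features respects the view contract", {
  set.seed(15)
  simT <- simulate_tendon_image(tendon_image_params(view = "transverse"),
                                seed = 20)
  simL <- simulate_tendon_image(tendon_image_params(view = "longitudinal"),
                                seed = 21)
  cfg <- qus_config(d = 5)

  fsT <- extract_features(simT$image, simT$roi, cfg)
  expect_setequal(qus_feature_names("transverse"),
                  c("thickness_cm", "width_cm", "area_cm2", "echogenicity",
                    "variance", "skewness", "kurtosis", "entropy",
                    "contrast", "energy", "homogeneity"))
  expect_false(any(vapply(qus_feature_names("transverse"),
                          function(f) is.null(fsT[[f]]), logical(1))))

  fsL <- extract_features(simL$image, simL$roi, cfg)
  expect_null(fsL$width_cm)
  expect_null(fsL$area_cm2)
  expect_false(is.null(fsL$thickness_cm))

  expect_error(extract_features(simT$image, simL$roi, cfg), "view mismatch")

  # entropy mode switch picks histogram vs co-occurrence entropy
  fsH <- extract_features(simL$image, simL$roi, qus_config(d = 5))
  fsC <- extract_features(simL$image, simL$roi,
                          qus_config(d = 5, entropy_mode = "cooccurrence"))
  expect_equal(fsH$entropy, fsH$detail$entropy_histogram)
  expect_equal(fsC$entropy, fsC$detail$entropy_cooccurrence)
  expect_lte(fsH$detail$entropy_histogram, 8)

  rows <- features_to_rows(fsL, meta = list(tendon_id = "t1", group = "g"))
  expect_equal(nrow(rows), 9L)
  expect_true(all(c("tendon_id", "feature", "value", "undefined_flag")
                  %in% names(rows)))
})

test_that("geometric ground truth round-trips through the phantom", {
  for (cond in c("healthy", "pathologic")) {
    simL <- simulate_tendon_image(
      tendon_image_params(view = "longitudinal", condition = cond), seed = 30)
    fs <- extract_features(simL$image, simL$roi, qus_config(d = 5))
    expect_lt(abs(fs$thickness_cm - simL$truth$thickness_cm) /
                simL$truth$thickness_cm, 0.02)

    simT <- simulate_tendon_image(
      tendon_image_params(view = "transverse", condition = cond), seed = 31)
    fsT <- extract_features(simT$image, simT$roi, qus_config(d = 5))
    expect_lt(abs(fsT$thickness_cm - simT$truth$thickness_cm) /
                simT$truth$thickness_cm, 0.02)
    expect_lt(abs(fsT$width_cm - simT$truth$width_cm) /
                simT$truth$width_cm, 0.02)
    expect_lt(abs(fsT$area_cm2 - simT$truth$area_cm2) /
                simT$truth$area_cm2, 0.02)
  }
})
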