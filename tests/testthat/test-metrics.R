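test_that("sRGB to CIELAB lightness matches the closed-form oracle", {
  lab_L <- function(r, g, b) unname(srgb_to_lab(matrix(c(r, g, b), 1))[1, "L"])
  expect_equal(lab_L(255, 255, 255), 100, tolerance = 1e-6)
  expect_equal(lab_L(0, 0, 0), 0, tolerance = 1e-9)
  expect_equal(lab_L(119, 119, 119), oracle_lab_L(119, 119, 119),
               tolerance = 1e-6)

  set.seed(14)
  rgb <- matrix(round(runif(300, 0, 255)), ncol = 3)
  got <- unname(srgb_to_lab(rgb)[, "L"])
  want <- vapply(seq_len(nrow(rgb)),
                 function(i) oracle_lab_L(rgb[i, 1], rgb[i, 2], rgb[i, 3]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-6)

  # coarse agreement with the independent grDevices conversion
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(got - ref[, 1])), 0.5)
})

test_that("mean_luminosity averages L over the ROI only", {
  img <- disc_image(40, 50, radius = 12, value = 255)
  mask <- detect_roi(img, threshold = 20)
  expect_equal(mean_luminosity(img, mask), 100, tolerance = 1e-6)
  expect_error(mean_luminosity(img, matrix(FALSE, 40, 50)), "empty")
})

test_that("global contrast factor: constant images and checkerboards", {
  mask <- matrix(TRUE, 16, 16)
  img <- grey_image(matrix(80, 16, 16))
  expect_equal(global_contrast_factor(img, mask), 0)

  # 1-pixel checkerboard: coarser levels average to a constant, so only the
  # finest level contributes; its per-pixel contrast comes from a
  # brute-force loop over the 8-neighborhoods (diagonal neighbors share the
  # cell parity, so the interior local contrast is |La - Lb| / 2)
  cb <- matrix(60, 16, 16)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 180
  img <- grey_image(cb)
  La <- unname(srgb_to_lab(matrix(c(60, 60, 60), 1))[1, "L"]) / 100
  Lb <- unname(srgb_to_lab(matrix(c(180, 180, 180), 1))[1, "L"]) / 100
  L <- matrix(La, 16, 16); L[(row(L) + col(L)) %% 2 == 0] <- Lb
  lc <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) {
    ds <- c()
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      y <- i + dy; x <- j + dx
      if (y >= 1 && y <= 16 && x >= 1 && x <= 16)
        ds <- c(ds, abs(L[i, j] - L[y, x]))
    }
    lc[i, j] <- mean(ds)
  }
  expect_equal(lc[8, 8], abs(La - Lb) / 2)  # interior hand value
  expect_equal(global_contrast_factor(img, mask), 0.12 * mean(lc),
               tolerance = 1e-9)

  # doubling the weights doubles the metric
  g1 <- global_contrast_factor(img, mask)
  g2 <- global_contrast_factor(img, mask,
                               weights = 2 * c(0.12, 0.142, 0.154))
  expect_equal(g2, 2 * g1)
})

test_that("local contrast is translation-invariant in lightness", {
  set.seed(8)
  L <- matrix(runif(100), 10, 10)
  mask <- random_mask(10, 10)
  expect_equal(fundusbf:::local_contrast_mean(L, mask),
               fundusbf:::local_contrast_mean(L + 0.3, mask),
               tolerance = 1e-12)
  # linear scaling of lightness contrast scales the metric
  expect_equal(fundusbf:::local_contrast_mean(0.5 * L, mask),
               0.5 * fundusbf:::local_contrast_mean(L, mask),
               tolerance = 1e-12)
})

test_that("GCF excludes off-ROI neighbors from the local contrasts", {
  # two-column ROI bordered by black: off-ROI black must not inflate contrast
  m <- matrix(FALSE, 10, 10); m[, 5:6] <- TRUE
  ch <- matrix(0, 10, 10); ch[m] <- 200
  # the thin ROI vanishes at the coarsest level, which is reported
  expect_warning(g <- global_contrast_factor(grey_image(ch), m),
                 "vanished at resolution level 3")
  expect_equal(g, 0)  # constant within the ROI
})

test_that("relative gains follow the percent-change formula", {
  expect_equal(relative_gain(50, 50), 0)
  expect_equal(relative_gain(50, 75), 50)
  expect_error(relative_gain(0, 10), "strictly positive")
  # gain composes: inverting the gain recovers the baseline
  g <- relative_gain(35.92, 59.44)
  expect_equal(59.44 / (1 + g / 100), 35.92)
})

test_that("average_report averages fields and recomputes gains", {
  r1 <- quality_report(30, 0.4, 60, 1.2)
  expect_equal(average_report(list(r1))[
    c("luminosity_before", "contrast_before", "luminosity_after",
      "contrast_after", "luminosity_gain_pct", "contrast_gain_pct")],
    r1[c("luminosity_before", "contrast_before", "luminosity_after",
         "contrast_after", "luminosity_gain_pct", "contrast_gain_pct")])
  r2 <- quality_report(50, 0.6, 70, 1.0)
  avg <- average_report(list(r1, r2))
  expect_equal(avg$luminosity_before, 40)
  expect_equal(avg$luminosity_gain_pct, relative_gain(40, 65))
  expect_equal(avg$contrast_gain_pct, relative_gain(0.5, 1.1))
  expect_error(average_report(list()), "empty")
})
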