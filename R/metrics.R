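# Quality metrics: mean CIELAB lightness over the ROI, a three-resolution
# global contrast factor, and the relative gain formulas used to compare
# the input with its enhanced version.

#' Convert 8-bit sRGB triplets to CIELAB
#'
#' Standard sRGB (D65) conversion: inverse sRGB companding, the sRGB
#' RGB-to-XYZ matrix, then CIE L*a*b* with the D65 reference white.
#' Vectorized over rows.
#'
#' @param rgb Numeric matrix with columns R, G, B in \[0, 255\].
#' @return Numeric matrix with columns `L` (0-100), `a`, `b`.
#' @export
srgb_to_lab <- function(rgb) {
  stopifnot(is.matrix(rgb), ncol(rgb) == 3)
  x <- rgb / 255
  lin <- ifelse(x <= 0.04045, x / 12.92, ((x + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- lin %*% t(M)
  white <- c(0.95047, 1, 1.08883)
  t3 <- sweep(xyz, 2, white, "/")
  d <- 6 / 29
  f <- ifelse(t3 > d^3, t3^(1 / 3), t3 / (3 * d^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' Mean CIELAB lightness over the ROI
#'
#' @param image A [fundus_image()].
#' @param mask Logical ROI matrix.
#' @return Mean `L` (0-100 scale) over ROI pixels.
#' @export
mean_luminosity <- function(image, mask) {
  stopifnot(inherits(image, "fundus_image"),
            identical(dim(mask), dim(image$green)))
  if (!any(mask)) stop("mask is empty")
  rgb <- cbind(image$red[mask], image$green[mask], image$blue[mask])
  mean(srgb_to_lab(rgb)[, 1])
}

# lightness map in [0, 1] for the contrast metric
lightness_map <- function(image) {
  rgb <- cbind(as.vector(image$red), as.vector(image$green),
               as.vector(image$blue))
  matrix(srgb_to_lab(rgb)[, 1] / 100, image$height, image$width)
}

# mean |L - neighbor L| against in-ROI 8-neighbors, then mean over ROI
local_contrast_mean <- function(L, mask) {
  h <- nrow(L); w <- ncol(L)
  m <- mask * 1
  Lm <- L * m
  dsum <- matrix(0, h, w); dcnt <- dsum
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- shift_matrix(Lm, dy, dx)
    nm <- shift_matrix(m, dy, dx)
    dsum <- dsum + abs(L * nm - nb)
    dcnt <- dcnt + nm
  }
  lc <- matrix(0, h, w)
  ok <- mask & dcnt > 0
  lc[ok] <- dsum[ok] / dcnt[ok]
  mean(lc[mask])
}

# 2x2 superpixel average of a matrix (odd trailing row/col dropped)
downsample2 <- function(m) {
  h2 <- nrow(m) %/% 2L; w2 <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h2), seq_len(2L * w2), drop = FALSE]
  (m[seq(1, 2 * h2, 2), seq(1, 2 * w2, 2), drop = FALSE] +
   m[seq(2, 2 * h2, 2), seq(1, 2 * w2, 2), drop = FALSE] +
   m[seq(1, 2 * h2, 2), seq(2, 2 * w2, 2), drop = FALSE] +
   m[seq(2, 2 * h2, 2), seq(2, 2 * w2, 2), drop = FALSE]) / 4
}

#' Multi-resolution global contrast factor over the ROI
#'
#' The image is converted to perceptual lightness (CIELAB `L` rescaled to
#' \[0, 1\]). At each of `length(weights)` resolutions the local contrast of
#' a pixel is the mean absolute lightness difference against its in-ROI
#' 8-neighbors, the level contrast is the mean local contrast over ROI
#' pixels, and the global contrast factor is the weight-sum of the level
#' contrasts. Coarser levels are formed by 2x2 superpixel averaging of the
#' lightness and of the ROI fraction; a superpixel is in-ROI when its mask
#' fraction exceeds 0.5. A level whose mask vanishes contributes 0 with a
#' warning.
#'
#' @param image A [fundus_image()].
#' @param mask Logical ROI matrix.
#' @param weights Per-resolution weights (default `c(0.12, 0.142, 0.154)`).
#' @return The global contrast factor (dimensionless).
#' @export
global_contrast_factor <- function(image, mask,
                                   weights = c(0.12, 0.142, 0.154)) {
  stopifnot(inherits(image, "fundus_image"),
            identical(dim(mask), dim(image$green)),
            is.numeric(weights), length(weights) >= 1, all(weights > 0))
  if (!any(mask)) stop("mask is empty")
  L <- lightness_map(image)
  frac <- mask * 1
  gcf <- 0
  for (r in seq_along(weights)) {
    m <- frac > 0.5
    if (!any(m)) {
      warning("ROI mask vanished at resolution level ", r,
              "; level contributes 0")
    } else {
      gcf <- gcf + weights[r] * local_contrast_mean(L, m)
    }
    if (r < length(weights)) {
      L <- downsample2(L)
      frac <- downsample2(frac)
    }
  }
  gcf
}

#' Relative gain in percent
#'
#' `(after - before) / before * 100`, the luminosity- and contrast-gain
#' formula of the evaluation protocol.
#'
#' @param before,after Positive scalars (before must be strictly positive).
#' @return Gain in percent.
#' @export
relative_gain <- function(before, after) {
  if (!is.numeric(before) || length(before) != 1L || !is.finite(before) ||
      before <= 0)
    stop("gain undefined: baseline value must be strictly positive, got ",
         deparse(before))
  (after - before) / before * 100
}

#' Assemble a quality report
#'
#' Bundles before/after mean lightness and global contrast factor with the
#' corresponding relative gains.
#'
#' @param luminosity_before,luminosity_after Mean CIELAB `L` (0-100).
#' @param contrast_before,contrast_after Global contrast factors.
#' @param filter_descriptor Optional record of the background filter used.
#' @param sample Optional sample label.
#' @return A `quality_report` object.
#' @export
quality_report <- function(luminosity_before, contrast_before,
                           luminosity_after, contrast_after,
                           filter_descriptor = NULL, sample = NA_character_) {
  structure(list(
    sample = sample,
    luminosity_before = luminosity_before,
    contrast_before = contrast_before,
    luminosity_after = luminosity_after,
    contrast_after = contrast_after,
    luminosity_gain_pct = relative_gain(luminosity_before, luminosity_after),
    contrast_gain_pct = relative_gain(contrast_before, contrast_after),
    filter_descriptor = filter_descriptor
  ), class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<quality_report%s: L %.2f -> %.2f (%+.1f%%), ",
    "C %.3f -> %.3f (%+.1f%%)>\n"),
    if (is.na(x$sample)) "" else paste0(" ", x$sample),
    x$luminosity_before, x$luminosity_after, x$luminosity_gain_pct,
    x$contrast_before, x$contrast_after, x$contrast_gain_pct))
  invisible(x)
}

#' Average a list of quality reports
#'
#' Arithmetic mean of each before/after field; the gains are recomputed from
#' the averaged before/after values (not averaged themselves).
#'
#' @param reports Nonempty list of `quality_report` objects.
#' @return A `quality_report` labelled `"average"`.
#' @export
average_report <- function(reports) {
  if (length(reports) == 0L) stop("cannot average an empty list of reports")
  stopifnot(all(vapply(reports, inherits, logical(1), "quality_report")))
  f <- function(field) mean(vapply(reports, `[[`, numeric(1), field))
  quality_report(
    luminosity_before = f("luminosity_before"),
    contrast_before = f("contrast_before"),
    luminosity_after = f("luminosity_after"),
    contrast_after = f("contrast_after"),
    filter_descriptor = reports[[1]]$filter_descriptor,
    sample = "average"
  )
}

#' @export
as.data.frame.quality_report <- function(x, ...) {
  data.frame(
    sample = x$sample,
    L_before = x$luminosity_before, C_before = x$contrast_before,
    L_after = x$luminosity_after, C_after = x$contrast_after,
    L_gain_pct = x$luminosity_gain_pct, C_gain_pct = x$contrast_gain_pct,
    filter = if (is.null(x$filter_descriptor)) NA_character_ else
      x$filter_descriptor$family,
    stringsAsFactors = FALSE
  )
}
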