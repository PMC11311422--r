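# Synthetic fundus phantoms.
#
# Deterministic, seeded generator of fundus-like images with known ground
# truth, so every pipeline stage can be validated without clinical data.
# A phantom is a bright disc (the eye region) on a black surround, carrying
# smooth non-uniform illumination (linear gradient plus an optional bright
# reflection bump centered on the ROI border), dark curvilinear vessels,
# small bright exudate spots, and clipped Gaussian noise. Background channel
# means are ordered R >= G >= B, the usual fundus color balance.

#' Specification of a synthetic fundus phantom
#'
#' Defaults describe a dim, boundary-reflection-affected fundus photograph
#' of the size the enhancement pipeline targets (500 x 700): base color
#' (120, 80, 50), an illumination gradient spanning 40 levels across the ROI
#' diameter, a border reflection bump of amplitude 60 and spatial scale 80
#' px, five vessels of width 3 darkened by 40 levels, eight exudates of
#' radius 6 brightened by 70 levels, and clipped Gaussian noise of sd 1.
#'
#' @param height,width Image size in pixels (default 500 x 700).
#' @param roi_radius_fraction ROI disc radius as a fraction of the smaller
#'   image dimension (default 0.48).
#' @param base Named per-channel background levels, must satisfy
#'   `r >= g >= b`.
#' @param gradient_amplitude Illumination span (levels) across the ROI
#'   diameter; applied equally to all channels.
#' @param gradient_angle Gradient direction in radians, or `NULL` to draw it
#'   from the seed.
#' @param reflection `NULL` for none, or a list with `amplitude` (levels),
#'   `scale` (Gaussian sd, px) and optional `angle` (position of the bump
#'   center on the ROI border; drawn from the seed when absent).
#' @param vessels List with `count`, `width` (px) and `darkness` (levels).
#' @param exudates List with `count`, `radius` (px) and `brightness` (levels).
#' @param noise_sd Gaussian noise sd in levels (clipped with the image).
#' @param seed Integer seed; the same spec always generates bit-identical
#'   integer images.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 500, width = 700,
                         roi_radius_fraction = 0.48,
                         base = c(r = 120, g = 80, b = 50),
                         gradient_amplitude = 40,
                         gradient_angle = NULL,
                         reflection = list(amplitude = 60, scale = 80),
                         vessels = list(count = 5, width = 3, darkness = 40),
                         exudates = list(count = 8, radius = 6, brightness = 70),
                         noise_sd = 1,
                         seed = 1L) {
  stopifnot(height >= 16, width >= 16,
            roi_radius_fraction > 0, roi_radius_fraction <= 0.5,
            all(c("r", "g", "b") %in% names(base)),
            noise_sd >= 0, noise_sd <= 2)
  if (!(base["r"] >= base["g"] && base["g"] >= base["b"]))
    stop("background channel means must be ordered r >= g >= b")
  structure(list(
    height = as.integer(height), width = as.integer(width),
    roi_radius_fraction = roi_radius_fraction, base = base,
    gradient_amplitude = gradient_amplitude, gradient_angle = gradient_angle,
    reflection = reflection, vessels = vessels, exudates = exudates,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_spec")
}

disc_mask <- function(h, w, cy, cx, radius) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  (X - cx)^2 + (Y - cy)^2 <= radius^2
}

stamp_disc <- function(mask, cy, cx, radius) {
  h <- nrow(mask); w <- ncol(mask)
  ys <- max(1, floor(cy - radius)):min(h, ceiling(cy + radius))
  xs <- max(1, floor(cx - radius)):min(w, ceiling(cx + radius))
  for (y in ys) for (x in xs)
    if ((x - cx)^2 + (y - cy)^2 <= radius^2) mask[y, x] <- TRUE
  mask
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' Deterministic for a fixed spec: the RNG state is saved, seeded from
#' `spec$seed` and restored on exit. The returned truth contains the clean
#' per-channel background surfaces (illumination only, before foreground and
#' noise), the ROI mask and the foreground (vessel + exudate) mask, so
#' background-recovery and equalization properties can be checked against
#' known values.
#'
#' @param spec A [phantom_spec()].
#' @return A `fundus_phantom` list: `image` ([fundus_image()], integer
#'   levels), `roi` (logical), `true_background` (list of matrices `red`,
#'   `green`, `blue`; 0 outside the ROI), `foreground_mask` (logical),
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  h <- spec$height; w <- spec$width
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  radius <- spec$roi_radius_fraction * min(h, w)
  roi <- disc_mask(h, w, cy, cx, radius)
  if (!any(roi)) stop("invalid phantom spec: geometry leaves no ROI")

  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)

  theta <- if (is.null(spec$gradient_angle)) stats::runif(1, 0, 2 * pi) else
    spec$gradient_angle
  illum <- spec$gradient_amplitude *
    ((X - cx) * cos(theta) + (Y - cy) * sin(theta)) / (2 * radius)

  if (!is.null(spec$reflection)) {
    phi <- if (is.null(spec$reflection$angle)) stats::runif(1, 0, 2 * pi) else
      spec$reflection$angle
    rcx <- cx + radius * cos(phi)
    rcy <- cy + radius * sin(phi)
    d2 <- (X - rcx)^2 + (Y - rcy)^2
    illum <- illum + spec$reflection$amplitude *
      exp(-d2 / (2 * spec$reflection$scale^2))
  }

  bg <- list(red = spec$base[["r"]] + illum,
             green = spec$base[["g"]] + illum,
             blue = spec$base[["b"]] + illum)

  fg <- matrix(FALSE, h, w)
  delta <- list(red = matrix(0, h, w), green = matrix(0, h, w),
                blue = matrix(0, h, w))

  # vessels: smooth random walks stamped with a disc of the vessel width
  vs <- spec$vessels
  if (!is.null(vs) && vs$count > 0) {
    vmask <- matrix(FALSE, h, w)
    for (v in seq_len(vs$count)) {
      a0 <- stats::runif(1, 0, 2 * pi)
      r0 <- radius * sqrt(stats::runif(1, 0, 0.6))
      py <- cy + r0 * sin(a0); px <- cx + r0 * cos(a0)
      dir <- stats::runif(1, 0, 2 * pi)
      nsteps <- round(2 * radius)
      for (s in seq_len(nsteps)) {
        dir <- dir + stats::rnorm(1, 0, 0.12)
        py <- py + sin(dir); px <- px + cos(dir)
        if ((px - cx)^2 + (py - cy)^2 > (0.95 * radius)^2) break
        vmask <- stamp_disc(vmask, py, px, vs$width / 2)
      }
    }
    vmask <- vmask & roi
    fg <- fg | vmask
    for (ch in names(delta)) delta[[ch]][vmask] <- delta[[ch]][vmask] - vs$darkness
  }

  # exudates: small bright discs, yellowish (strong in red/green, weak in blue)
  ex <- spec$exudates
  if (!is.null(ex) && ex$count > 0) {
    for (e in seq_len(ex$count)) {
      a0 <- stats::runif(1, 0, 2 * pi)
      r0 <- (radius - 2 * ex$radius) * sqrt(stats::runif(1))
      ey <- cy + r0 * sin(a0); ex0 <- cx + r0 * cos(a0)
      emask <- stamp_disc(matrix(FALSE, h, w), ey, ex0, ex$radius) & roi
      fg <- fg | emask
      delta$red[emask] <- delta$red[emask] + ex$brightness
      delta$green[emask] <- delta$green[emask] + ex$brightness
      delta$blue[emask] <- delta$blue[emask] + 0.3 * ex$brightness
    }
  }

  make_channel <- function(ch) {
    v <- bg[[ch]] + delta[[ch]]
    if (spec$noise_sd > 0) v <- v + stats::rnorm(h * w, 0, spec$noise_sd)
    v <- round(clamp255(v))
    v[!roi] <- 0
    v
  }
  image <- fundus_image(red = make_channel("red"),
                        green = make_channel("green"),
                        blue = make_channel("blue"))
  true_background <- lapply(bg, function(m) { m[!roi] <- 0; clamp255(m) })

  structure(list(image = image, roi = roi,
                 true_background = true_background,
                 foreground_mask = fg, spec = spec),
            class = "fundus_phantom")
}

#' @export
print.fundus_phantom <- function(x, ...) {
  cat(sprintf(
    "<fundus_phantom %d x %d, ROI %d px, foreground %.1f%% of ROI, seed %d>\n",
    x$spec$height, x$spec$width, sum(x$roi),
    100 * sum(x$foreground_mask) / sum(x$roi), x$spec$seed))
  invisible(x)
}
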