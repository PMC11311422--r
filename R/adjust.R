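# Luminosity adjustment.
#
# The difference between a channel value and its background brightness is the
# channel "gap": the signal a pixel carries on top of the local illumination.
# Adjustment keeps each pixel's gap but moves the background level of every
# ROI pixel to a common baseline (128 by default), so the adjusted channel
# has uniform background luminosity:
#
#   A(x,y) = baseline + channel(x,y) - BB(x,y).
#
# Arithmetic is done in signed reals and only then clamped to [0, 255]; the
# gap is preserved exactly wherever no clamping occurs.

#' Level the background luminosity of one channel
#'
#' @param channel Numeric matrix (the channel after the 3x3 pre-filter).
#' @param surface Background-brightness surface from [estimate_background()]
#'   or [masked_median_surface()].
#' @param mask Logical ROI matrix.
#' @param baseline Target background level (default 128).
#' @return Numeric matrix: `clamp(baseline + channel - surface, 0, 255)` on
#'   the ROI, 0 outside.
#' @export
adjust_channel <- function(channel, surface, mask, baseline = 128) {
  stopifnot(is.matrix(channel),
            identical(dim(channel), dim(surface)),
            identical(dim(channel), dim(mask)))
  out <- matrix(0, nrow(channel), ncol(channel))
  out[mask] <- clamp255(baseline + channel[mask] - surface[mask])
  out
}

#' Adjusted green channel with full information
#'
#' The red channel is volatile (most foreground objects are strongly red) and
#' the blue channel tracks the background; adding all three channel gaps to
#' the baseline builds a green-channel substitute with improved contrast and
#' stability:
#'
#'   `AGF = baseline + (R - BBR) + (G - BBG) + (B - BBB)`.
#'
#' @param image A [fundus_image()] whose channels are the pre-filtered R, G, B.
#' @param surfaces List of three background surfaces named `red`, `green`,
#'   `blue`.
#' @param mask Logical ROI matrix.
#' @param baseline Target background level (default 128).
#' @return Numeric matrix, clamped to \[0, 255\] on the ROI, 0 outside.
#' @export
adjust_green_full <- function(image, surfaces, mask, baseline = 128) {
  stopifnot(inherits(image, "fundus_image"),
            all(c("red", "green", "blue") %in% names(surfaces)))
  gap <- (image$red[mask] - surfaces$red[mask]) +
    (image$green[mask] - surfaces$green[mask]) +
    (image$blue[mask] - surfaces$blue[mask])
  out <- matrix(0, image$height, image$width)
  out[mask] <- clamp255(baseline + gap)
  out
}
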