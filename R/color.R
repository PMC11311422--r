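# Color correction.
#
# Recombining independently equalized channels produces peculiar color
# tones, so the enhanced green channel is the single anchor: the new red and
# blue channels are the stored per-pixel R/G and B/G ratios multiplied by
# the equalized green, which preserves each pixel's original hue.

#' Rebuild the color image from the equalized green channel
#'
#' On every ROI pixel: `Rnew = r_over_g * eg`, `Bnew = b_over_g * eg`,
#' `Gnew = eg`, each rounded to the nearest integer (half away from zero)
#' and clamped to \[0, 255\]. Extreme products saturate rather than rescale,
#' accepting a minor hue shift at specular pixels. Off-ROI pixels are black.
#'
#' @param eg Numeric matrix: the equalized green channel.
#' @param ratios A `ratio_maps` object from [compute_ratio_maps()].
#' @param mask Logical ROI matrix.
#' @return A [fundus_image()].
#' @export
recombine <- function(eg, ratios, mask) {
  stopifnot(is.matrix(eg), inherits(ratios, "ratio_maps"),
            identical(dim(eg), dim(mask)),
            identical(dim(eg), dim(ratios$r_over_g)))
  round_half_up <- function(x) floor(x + 0.5)
  h <- nrow(eg); w <- ncol(eg)
  r <- matrix(0, h, w); g <- r; b <- r
  r[mask] <- clamp255(round_half_up(ratios$r_over_g[mask] * eg[mask]))
  b[mask] <- clamp255(round_half_up(ratios$b_over_g[mask] * eg[mask]))
  g[mask] <- clamp255(round_half_up(eg[mask]))
  fundus_image(red = r, green = g, blue = b)
}
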