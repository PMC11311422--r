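# Constrained ROI-wide histogram equalization.
#
# The adjusted green channel is equalized over the whole ROI as a single
# tile (no spatial tiling or interpolation), under two constraints that
# protect detail:
#   * the number of distinct grey levels is maintained (the mapping is
#     strictly increasing over the occupied levels), and
#   * the gap between consecutive occupied levels may grow but never shrink.
# Contrast amplification is limited by clipping each histogram bin at
# clip_factor times the uniform occupancy (pixel count / occupied levels),
# with the clipped excess redistributed uniformly over the occupied bins in
# one pass.

#' Build the constrained equalization level mapping
#'
#' Steps: (a) 256-bin histogram over ROI pixels (values rounded to integers
#' in \[0, 255\] on entry); (b) clip each occupied bin at
#' `clip_factor * pixel_count / occupied_bins` and redistribute the excess
#' uniformly over occupied bins (single pass); (c) map the cumulative
#' distribution to \[0, 255\]; (d) enforce the gap constraint left to right:
#' `out[k] = max(cdf_target[k], out[k-1] + (in[k] - in[k-1]))`; (e) if the
#' top level then exceeds 255, shrink the output gaps by the largest common
#' factor that keeps every output gap at least its input gap (found by
#' bisection), shifting down if needed — the input gaps themselves always
#' fit in \[0, 255\].
#'
#' @param channel Numeric matrix (typically the adjusted green channel).
#' @param mask Logical ROI matrix.
#' @param clip_factor Histogram clip limit as a multiple of the uniform
#'   occupancy (default 2).
#' @return A `level_mapping` object: sorted `input_levels`, matching strictly
#'   increasing `output_levels` in \[0, 255\].
#' @export
build_constrained_mapping <- function(channel, mask, clip_factor = 2) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)))
  vals <- clamp255(round(channel[mask]))
  if (length(vals) == 0L) stop("mask is empty")
  hist256 <- tabulate(vals + 1L, nbins = 256L)
  occ <- which(hist256 > 0L)
  input_levels <- occ - 1L
  nlev <- length(occ)
  if (nlev == 1L) {
    # degenerate histogram: no spread possible without changing level count
    return(new_level_mapping(input_levels, input_levels, clip_factor))
  }
  counts <- hist256[occ]
  npix <- sum(counts)
  clip_limit <- clip_factor * npix / nlev
  clipped <- pmin(counts, clip_limit)
  excess <- sum(counts - clipped)
  clipped <- clipped + excess / nlev
  cdf <- cumsum(clipped) / sum(clipped)
  target <- floor(255 * cdf + 1e-9)

  in_gaps <- diff(input_levels)
  out <- numeric(nlev)
  out[1] <- target[1]
  for (k in 2:nlev) out[k] <- max(target[k], out[k - 1] + in_gaps[k - 1])

  if (out[nlev] > 255) {
    out_gaps <- diff(out)
    total <- function(f) out[1] + sum(pmax(in_gaps, f * out_gaps))
    if (total(0) > 255) {
      # even the input gaps overflow from this anchor: lower the anchor and
      # keep the input gaps verbatim (they always span at most 255)
      out <- (255 - sum(in_gaps)) + c(0, cumsum(in_gaps))
    } else {
      lo <- 0; hi <- 1
      for (i in 1:60) {
        mid <- (lo + hi) / 2
        if (total(mid) > 255) hi <- mid else lo <- mid
      }
      out <- out[1] + c(0, cumsum(pmax(in_gaps, lo * out_gaps)))
    }
  }
  new_level_mapping(input_levels, out, clip_factor)
}

new_level_mapping <- function(input_levels, output_levels, clip_factor) {
  stopifnot(length(input_levels) == length(output_levels),
            !is.unsorted(input_levels, strictly = TRUE),
            !is.unsorted(output_levels, strictly = TRUE),
            all(output_levels >= 0), all(output_levels <= 255))
  structure(list(input_levels = as.numeric(input_levels),
                 output_levels = as.numeric(output_levels),
                 clip_factor = clip_factor),
            class = "level_mapping")
}

#' @export
print.level_mapping <- function(x, ...) {
  n <- length(x$input_levels)
  cat(sprintf("<level_mapping: %d levels, [%g, %g] -> [%.1f, %.1f]>\n",
              n, x$input_levels[1], x$input_levels[n],
              x$output_levels[1], x$output_levels[n]))
  invisible(x)
}

#' Apply a level mapping to the ROI of a channel
#'
#' Replaces every ROI pixel value by its mapped level; off-ROI pixels are
#' left untouched (0 in the pipeline). The number of distinct ROI levels is
#' preserved because the mapping is strictly increasing.
#'
#' @param channel Numeric matrix; ROI values are rounded to integers before
#'   lookup and must all be present in the mapping.
#' @param mask Logical ROI matrix.
#' @param mapping A `level_mapping` from [build_constrained_mapping()].
#' @return Numeric matrix.
#' @export
apply_mapping <- function(channel, mask, mapping) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)),
            inherits(mapping, "level_mapping"))
  idx <- match(clamp255(round(channel[mask])), mapping$input_levels)
  if (anyNA(idx))
    stop("internal consistency error: ROI contains levels absent from the mapping")
  out <- channel
  out[mask] <- mapping$output_levels[idx]
  out
}
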