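# ROI localization and pre-filtering.
#
# The eye region of a fundus photograph is a bright, roughly circular area on
# a near-black surround. It is localized by thresholding the channel-mean
# image, reduced to the largest 4-connected component with interior holes
# filled, and mirror-symmetrized about the vertical center line. All later
# pipeline math is restricted to this mask.

# shift a matrix by (dy, dx), padding with `fill`
shift_matrix <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) > 0 && length(xs) > 0)
    out[ys, xs] <- m[ys - dy, xs - dx, drop = FALSE]
  out
}

#' Detect the eye region (ROI) of a fundus image
#'
#' Thresholds the channel-mean intensity, keeps the largest 4-connected
#' component, fills interior holes, and symmetrizes the mask about the
#' vertical center line by taking the union with its left-right mirror
#' (so a reflection-clipped ROI is never shrunk).
#'
#' @param image A [fundus_image()].
#' @param threshold Intensity cut on the channel mean, in 8-bit units
#'   (default 20). Fundus surrounds are near-black, so a low fixed cut is
#'   robust; the value is exposed for unusual acquisitions.
#' @param largest_component Keep only the largest 4-connected component
#'   (default `TRUE`).
#' @param fill_holes Fill interior holes of the mask (default `TRUE`).
#' @param symmetrize Union with the left-right mirror (default `TRUE`).
#' @return Logical matrix of the image shape: `TRUE` inside the ROI.
#' @export
detect_roi <- function(image, threshold = 20, largest_component = TRUE,
                       fill_holes = TRUE, symmetrize = TRUE) {
  stopifnot(inherits(image, "fundus_image"))
  bw <- channel_mean_image(image) > threshold
  if (!any(bw))
    stop("ROI not found: no pixel exceeds threshold ", threshold)
  if (largest_component) {
    lab <- .label_components4(bw)
    sizes <- tabulate(lab[lab > 0L])
    bw <- lab == which.max(sizes)
  }
  if (fill_holes) bw <- .fill_holes(bw)
  if (symmetrize) bw <- bw | bw[, ncol(bw):1, drop = FALSE]
  bw
}

#' Per-pixel color ratio maps for later color correction
#'
#' Stores `R/G` and `B/G` at every ROI pixel before any filtering; the
#' enhanced green channel later anchors the color reconstruction through
#' these ratios. A zero or tiny green value is floored at `epsilon` so the
#' ratios stay finite and bounded by 255.
#'
#' @param image A [fundus_image()] (original, pre-filter channels).
#' @param mask ROI mask from [detect_roi()].
#' @param epsilon Green floor in intensity units (default 1).
#' @return A `ratio_maps` object with matrices `r_over_g` and `b_over_g`
#'   (ratio 1 outside the ROI).
#' @export
compute_ratio_maps <- function(image, mask, epsilon = 1) {
  stopifnot(inherits(image, "fundus_image"),
            identical(dim(mask), dim(image$green)))
  g <- pmax(image$green, epsilon)
  r_over_g <- matrix(1, image$height, image$width)
  b_over_g <- matrix(1, image$height, image$width)
  r_over_g[mask] <- image$red[mask] / g[mask]
  b_over_g[mask] <- image$blue[mask] / g[mask]
  structure(list(r_over_g = r_over_g, b_over_g = b_over_g, epsilon = epsilon),
            class = "ratio_maps")
}

#' ROI-masked 3x3 average filter
#'
#' Replaces every ROI pixel by the mean of the ROI-member pixels in its 3x3
#' neighborhood; off-ROI neighbors are excluded from both the sum and the
#' count, so values near the ROI border are not dragged toward the black
#' surround. Off-ROI pixels stay 0.
#'
#' @param channel Numeric matrix.
#' @param mask Logical ROI matrix of the same shape.
#' @return Numeric matrix; 0 outside the ROI.
#' @export
masked_average_3x3 <- function(channel, mask) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)))
  m <- mask * 1
  cm <- channel * m
  num <- matrix(0, nrow(channel), ncol(channel))
  den <- num
  for (dy in -1:1) for (dx in -1:1) {
    num <- num + shift_matrix(cm, dy, dx)
    den <- den + shift_matrix(m, dy, dx)
  }
  out <- matrix(0, nrow(channel), ncol(channel))
  out[mask] <- num[mask] / den[mask]
  out
}

#' Erode a mask by a square radius
#'
#' A pixel survives if the full `(2r+1) x (2r+1)` window around it lies
#' inside the mask (and inside the image). Computed exactly with an integral
#' image. Used to restrict evaluations to the ROI interior where the
#' background-estimation kernel has full support.
#'
#' @param mask Logical matrix.
#' @param radius Non-negative integer erosion radius.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(is.matrix(mask))
  r <- check_half_width(radius)
  if (r == 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  # integral image with a zero border
  s <- matrix(0, h + 1L, w + 1L)
  s[-1, -1] <- apply(apply(mask * 1, 2, cumsum), 1, cumsum) |> t()
  out <- matrix(FALSE, h, w)
  ys <- seq_len(h); xs <- seq_len(w)
  y0 <- pmax(ys - r, 1L); y1 <- pmin(ys + r, h)
  x0 <- pmax(xs - r, 1L); x1 <- pmin(xs + r, w)
  full <- as.numeric(2L * r + 1L)^2
  cnt <- s[y1 + 1L, x1 + 1L, drop = FALSE] - s[y0, x1 + 1L, drop = FALSE] -
    s[y1 + 1L, x0, drop = FALSE] + s[y0, x0, drop = FALSE]
  out[cnt == full] <- TRUE
  out
}
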