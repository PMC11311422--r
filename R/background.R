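# Background-brightness estimation.
#
# The background brightness BB(x,y) of a channel approximates the underlying
# illumination of the eye region, free of foreground objects (vessels,
# exudates, optic disc). It is computed by convolving the ROI with a large
# centrally peaked kernel under a boundary-aware rule: neighborhood pixels
# outside the ROI contribute neither to the weighted sum nor to the
# normalizer, so each output is the weighted mean of the in-ROI neighborhood
# members only. Out-of-image pixels are treated exactly like out-of-ROI
# pixels. The result is smoothed with the masked 3x3 average.

# linear (zero-padded) 2-D convolution via FFT, "same" output for an odd,
# centered kernel. Kernels used here are flip-symmetric, so convolution and
# correlation coincide.
conv2_same <- function(a, k) {
  h <- nrow(a); w <- ncol(a)
  kh <- nrow(k); kw <- ncol(k)
  wy <- (kh - 1L) %/% 2L; wx <- (kw - 1L) %/% 2L
  H <- stats::nextn(h + kh - 1L, c(2, 3, 5))
  W <- stats::nextn(w + kw - 1L, c(2, 3, 5))
  A <- matrix(0, H, W); A[1:h, 1:w] <- a
  K <- matrix(0, H, W); K[1:kh, 1:kw] <- k
  full <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (H * W)
  full[(wy + 1L):(wy + h), (wx + 1L):(wx + w), drop = FALSE]
}

#' ROI-masked, per-pixel renormalized convolution
#'
#' For every ROI pixel, forms the kernel-weighted sum over the neighborhood
#' members that lie inside the ROI (and inside the image) and divides by the
#' sum of exactly those kernel coefficients, so the effective weights always
#' sum to one. A constant channel is therefore reproduced exactly on any ROI
#' shape, and values near the ROI border are not biased toward the black
#' surround. Off-ROI output is 0.
#'
#' Implemented as the exact ratio of two zero-padded linear convolutions,
#' `conv(channel * mask, k) / conv(mask, k)`, which is algebraically
#' identical to dropping the out-of-ROI terms and renormalizing.
#'
#' @param channel Numeric matrix.
#' @param mask Logical ROI matrix of the same shape.
#' @param kernel A `bf_kernel` with strictly positive coefficients.
#' @return Numeric matrix; 0 outside the ROI.
#' @export
masked_normalized_convolve <- function(channel, mask, kernel) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)),
            inherits(kernel, "bf_kernel"))
  if (!any(mask)) stop("mask is empty")
  if (min(kernel$coefficients) <= 0)
    stop("kernel coefficients must be strictly positive")
  ksize <- 2L * kernel$half_width + 1L
  if (ksize > 2L * min(dim(channel)) + 1L)
    stop("kernel size ", ksize, " too large for a ",
         nrow(channel), "x", ncol(channel), " image")
  m <- mask * 1
  num <- conv2_same(channel * m, kernel$coefficients)
  den <- conv2_same(m, kernel$coefficients)
  out <- matrix(0, nrow(channel), ncol(channel))
  out[mask] <- num[mask] / den[mask]
  out
}

#' Estimate the background-brightness surface of a channel
#'
#' Runs [masked_normalized_convolve()] and smooths the result with the
#' ROI-masked 3x3 average, yielding the slowly varying background-brightness
#' surface `BB(x,y)`. ROI values are weighted means of in-ROI inputs, so they
#' stay inside the input's ROI value range (enforced against floating-point
#' round-off).
#'
#' @inheritParams masked_normalized_convolve
#' @return Numeric matrix (0 outside the ROI) with attributes
#'   `kernel_descriptor` (family/size/alpha/sigma of the kernel used).
#' @export
estimate_background <- function(channel, mask, kernel) {
  bb <- masked_normalized_convolve(channel, mask, kernel)
  bb <- masked_average_3x3(bb, mask)
  rng <- range(channel[mask])
  bb[mask] <- pmin(pmax(bb[mask], rng[1]), rng[2])
  attr(bb, "kernel_descriptor") <- list(
    family = kernel$family, size = 2L * kernel$half_width + 1L,
    alpha = kernel$alpha, sigma = kernel$sigma)
  bb
}

#' Histogram-based masked median background surface
#'
#' Baseline background estimator: each ROI pixel becomes the median of the
#' ROI-member values in its square window, computed with a sliding 256-bin
#' histogram (lower median on even member counts), then smoothed with the
#' masked 3x3 average so all baselines run in the same framework as the
#' binomial filter. Input values are rounded and clamped to integers in
#' \[0, 255\] on entry.
#'
#' @param channel Numeric matrix.
#' @param mask Logical ROI matrix.
#' @param window Odd window size (default 41).
#' @return Numeric matrix (0 outside the ROI) with a `kernel_descriptor`
#'   attribute.
#' @export
masked_median_surface <- function(channel, mask, window = 41) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(mask)))
  if (length(window) != 1L || window < 1 || window != floor(window) ||
      window %% 2 != 1)
    stop("window must be a single odd positive integer, got ", deparse(window))
  if (!any(mask)) stop("mask is empty")
  img <- matrix(as.integer(clamp255(round(channel))), nrow(channel))
  med <- .masked_median(img, mask, as.integer(window))
  bb <- masked_average_3x3(med, mask)
  attr(bb, "kernel_descriptor") <- list(
    family = "median", size = as.integer(window),
    alpha = NA_real_, sigma = NA_real_)
  bb
}
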