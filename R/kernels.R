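#' Smoothing kernels for background-brightness estimation
#'
#' The background of the eye region is estimated by convolving each color
#' channel with a large, centrally peaked smoothing kernel. The production
#' kernel is a flattened binomial filter; a scaled Gaussian and a flat
#' (box/average) kernel are provided as baselines for benchmarking.
#'
#' A kernel is a square, flip- and transpose-symmetric matrix of strictly
#' positive coefficients of size `(2w+1) x (2w+1)` whose maximum sits at the
#' center. Coefficients are kept as reals throughout; no integer quantization
#' is applied.
#'
#' @name kernels
NULL

new_kernel <- function(coefficients, family, alpha = NA_real_, sigma = NA_real_) {
  stopifnot(is.matrix(coefficients), nrow(coefficients) == ncol(coefficients))
  n <- nrow(coefficients)
  if (n %% 2L != 1L) stop("kernel size must be odd, got ", n)
  structure(
    list(
      coefficients = coefficients,
      half_width = (n - 1L) %/% 2L,
      family = family,
      alpha = alpha,
      sigma = sigma
    ),
    class = "bf_kernel"
  )
}

#' @export
print.bf_kernel <- function(x, ...) {
  n <- 2L * x$half_width + 1L
  cat(sprintf("<%s kernel %dx%d", x$family, n, n))
  if (!is.na(x$alpha)) cat(sprintf(", alpha=%g", x$alpha))
  if (!is.na(x$sigma)) cat(sprintf(", sigma=%g", x$sigma))
  cat(sprintf(", center=%g, min=%g>\n",
              x$coefficients[x$half_width + 1L, x$half_width + 1L],
              min(x$coefficients)))
  invisible(x)
}

check_half_width <- function(w) {
  if (length(w) != 1L || !is.numeric(w) || is.na(w) || w < 0 || w != floor(w))
    stop("half-width w must be a single non-negative integer, got ", deparse(w))
  as.integer(w)
}

#' Normalized 1-D binomial filter coefficients
#'
#' Builds the length `2w+1` binomial filter by cascaded convolution of the
#' vector `c(1, 1)` with itself `2w` times, i.e. row `2w` of Pascal's
#' triangle, then divides by the coefficient sum `4^w`. The accumulation is
#' done in exact integer arithmetic (adjacent-pair addition) before
#' normalization, so coefficients are exact up to `w = 26` where
#' `choose(52, 26)` is still below 2^53.
#'
#' @param w Non-negative integer half-width; the filter has `2w+1` taps.
#'   `w = 0` returns `1` (identity).
#' @return Numeric vector of `2w+1` coefficients summing to 1, palindromic,
#'   unimodal with the maximum at index `w + 1`.
#' @examples
#' binomial_1d(1)  # 0.25 0.50 0.25
#' binomial_1d(2) * 16  # 1 4 6 4 1
#' @export
binomial_1d <- function(w) {
  w <- check_half_width(w)
  v <- 1
  if (w > 0) {
    for (i in seq_len(2L * w)) v <- c(v, 0) + c(0, v)
  }
  v / sum(v)
}

#' 2-D binomial filter kernel
#'
#' Outer product of the 1-D binomial filter with itself, giving a separable
#' `(2w+1) x (2w+1)` kernel whose entries sum to 1.
#'
#' @inheritParams binomial_1d
#' @return A kernel object (class `bf_kernel`, family `"binomial"`).
#' @seealso [scale_and_flatten()] for the production scaling used before
#'   background estimation.
#' @export
binomial_2d <- function(w) {
  w <- check_half_width(w)
  if (w < 1) stop("2-D binomial kernel requires w >= 1")
  b <- binomial_1d(w)
  new_kernel(outer(b, b), family = "binomial")
}

#' Scale a kernel to a fixed maximum and flatten it
#'
#' Rescales the coefficients so the maximum equals `max_target`, multiplies by
#' the flattening factor `alpha`, and lower-limits every coefficient at
#' `floor`. This is the production post-processing of the binomial kernel:
#' the raw binomial filter is too peaky to capture the slowly varying
#' illumination trend, so it is scaled to a maximum of 100 with a minimum
#' floored at 1 and flattened by `alpha`. At `alpha * max_target <= floor`
#' every coefficient hits the floor and the kernel degenerates to a flat box.
#'
#' The order of operations (scale to max, multiply by alpha, then floor) is
#' the only one under which `alpha = 0.01` with the defaults forces all
#' coefficients to 1.
#'
#' @param kernel A `bf_kernel`.
#' @param alpha Flattening factor in `(0, 1]`. Values down to 0.01 are
#'   accepted; see the methods vignette for the discussion of the range.
#' @param max_target Target maximum coefficient before flattening (default 100).
#' @param floor Lower limit applied elementwise (default 1).
#' @return A `bf_kernel` with the same family, `alpha` recorded.
#' @examples
#' k <- scale_and_flatten(binomial_2d(1), alpha = 1)
#' k$coefficients  # 25 50 25 / 50 100 50 / 25 50 25
#' @export
scale_and_flatten <- function(kernel, alpha = 0.1, max_target = 100, floor = 1) {
  stopifnot(inherits(kernel, "bf_kernel"))
  if (length(alpha) != 1L || !is.numeric(alpha) || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1], got ", deparse(alpha))
  mx <- max(kernel$coefficients)
  if (!is.finite(mx) || mx <= 0) stop("kernel maximum must be strictly positive")
  co <- pmax(alpha * max_target * kernel$coefficients / mx, floor)
  new_kernel(co, family = kernel$family, alpha = alpha, sigma = kernel$sigma)
}

#' Scaled Gaussian baseline kernel
#'
#' Isotropic Gaussian `exp(-(m^2 + n^2) / (2 sigma^2))` evaluated on the
#' centered integer grid, scaled so the center coefficient equals
#' `max_target`, then floored. The defaults (41 taps, `sigma = 5`, maximum 10,
#' floor 1) reproduce the benchmark baseline: a Gaussian that is not too
#' peaky, scaled by 10 with the minimum limited to 1.
#'
#' @param size Odd kernel size (default 41).
#' @param sigma Spread in pixels (default 5).
#' @param max_target Center coefficient after scaling (default 10).
#' @param floor Elementwise lower limit (default 1).
#' @return A `bf_kernel` with family `"gaussian"`.
#' @export
gaussian_kernel <- function(size = 41, sigma = 5, max_target = 10, floor = 1) {
  if (length(size) != 1L || size < 1 || size != floor(size) || size %% 2 != 1)
    stop("size must be a single odd positive integer, got ", deparse(size))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number")
  w <- (size - 1) / 2
  g <- exp(-(seq(-w, w))^2 / (2 * sigma^2))
  co <- pmax(max_target * outer(g, g), floor)
  new_kernel(co, family = "gaussian", sigma = sigma)
}

#' Flat (box) average kernel
#'
#' All-ones kernel; the limit of the flattened binomial filter as
#' `alpha * max_target` falls to the floor.
#'
#' @param size Odd kernel size.
#' @return A `bf_kernel` with family `"average"`.
#' @export
average_kernel <- function(size = 41) {
  if (length(size) != 1L || size < 1 || size != floor(size) || size %% 2 != 1)
    stop("size must be a single odd positive integer, got ", deparse(size))
  new_kernel(matrix(1, size, size), family = "average")
}
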