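# Independent brute-force oracles. These deliberately use naive double
# loops and sorting, not the package's FFT/histogram code paths.

# masked renormalized neighborhood mean, direct O(n k^2) double loop.
# Written as correlation; the kernels under test are flip-symmetric, so
# correlation and convolution coincide.
oracle_masked_convolve <- function(channel, mask, k) {
  w <- (nrow(k) - 1) / 2
  h <- nrow(channel); wd <- ncol(channel)
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    if (!mask[i, j]) next
    s <- 0; d <- 0
    for (dy in -w:w) for (dx in -w:w) {
      y <- i + dy; x <- j + dx
      if (y < 1 || y > h || x < 1 || x > wd || !mask[y, x]) next
      co <- k[dy + w + 1, dx + w + 1]
      s <- s + co * channel[y, x]
      d <- d + co
    }
    out[i, j] <- s / d
  }
  out
}

# masked window median by explicit sort, lower median on even counts
oracle_masked_median <- function(channel, mask, window) {
  r <- (window - 1) / 2
  h <- nrow(channel); wd <- ncol(channel)
  out <- matrix(0, h, wd)
  for (i in seq_len(h)) for (j in seq_len(wd)) {
    if (!mask[i, j]) next
    ys <- max(1, i - r):min(h, i + r)
    xs <- max(1, j - r):min(wd, j + r)
    vals <- channel[ys, xs][mask[ys, xs]]
    vals <- sort(vals)
    out[i, j] <- vals[(length(vals) + 1) %/% 2]
  }
  out
}

# scalar step-by-step sRGB (D65) -> CIELAB lightness
oracle_lab_L <- function(r, g, b) {
  lin1 <- function(c) {
    c <- c / 255
    if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  R <- lin1(r); G <- lin1(g); B <- lin1(b)
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  t <- Y / 1
  d <- 6 / 29
  fy <- if (t > d^3) t^(1 / 3) else t / (3 * d^2) + 4 / 29
  116 * fy - 16
}

# brute-force square erosion
oracle_erode <- function(mask, r) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (i - r < 1 || i + r > h || j - r < 1 || j + r > w) next
    out[i, j] <- all(mask[(i - r):(i + r), (j - r):(j + r)])
  }
  out
}

# random connected-ish mask: a disc plus random noise pixels, never empty
random_mask <- function(h, w, p = 0.6) {
  m <- matrix(runif(h * w) < p, h, w)
  m[ceiling(h / 2), ceiling(w / 2)] <- TRUE
  m
}

# constant-value disc image on a black field
disc_image <- function(h, w, radius, value = 200, cy = (h + 1) / 2,
                       cx = (w + 1) / 2) {
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), w), h, w)
  d <- (X - cx)^2 + (Y - cy)^2 <= radius^2
  v <- matrix(0, h, w); v[d] <- value
  fundus_image(red = v, green = v, blue = v)
}

# single-channel grey fundus image from a matrix
grey_image <- function(m) {
  m <- pmin(pmax(m, 0), 255)
  fundus_image(red = m, green = m, blue = m)
}
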