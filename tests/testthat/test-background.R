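test_that("masked normalized convolution drops and renormalizes out-of-ROI terms", {
  # 1x3 ROI in a 3x3 image, binomial w=1 kernel: the in-ROI row of the
  # kernel is proportional to [1 2 1]
  mask <- matrix(FALSE, 3, 3); mask[2, ] <- TRUE
  ch <- matrix(0, 3, 3); ch[2, ] <- c(10, 20, 40)
  out <- masked_normalized_convolve(ch, mask, binomial_2d(1))
  expect_equal(out[2, 2], (10 + 2 * 20 + 40) / 4)
  expect_equal(out[2, 1], (2 * 10 + 20) / 3)
  expect_equal(out[2, 3], (20 + 2 * 40) / 3)
  expect_equal(out[!mask], rep(0, 6))
})

test_that("FFT route equals the double-loop oracle on random masked images", {
  set.seed(101)
  for (i in 1:12) {
    mask <- random_mask(12, 12)
    ch <- matrix(round(runif(144, 0, 255)), 12, 12)
    for (w in 1:3) {
      k <- scale_and_flatten(binomial_2d(w), alpha = 0.5)
      expect_equal(masked_normalized_convolve(ch, mask, k),
                   oracle_masked_convolve(ch, mask, k$coefficients),
                   tolerance = 1e-11)
    }
  }
})

test_that("constants are preserved exactly and outputs stay within ROI extrema", {
  set.seed(11)
  for (i in 1:5) {
    mask <- random_mask(20, 25, p = 0.5)
    ch <- matrix(0, 20, 25); ch[mask] <- 55
    k <- scale_and_flatten(binomial_2d(3), alpha = 0.1)
    bb <- estimate_background(ch, mask, k)
    expect_equal(bb[mask], rep(55, sum(mask)))
    ch[mask] <- runif(sum(mask), 10, 240)
    bb <- estimate_background(ch, mask, k)
    expect_gte(min(bb[mask]), min(ch[mask]))
    expect_lte(max(bb[mask]), max(ch[mask]))
  }
})

test_that("a linear ramp is reproduced in the interior of a full ROI", {
  h <- 30; w <- 40
  ramp <- matrix(rep(10 + 2 * seq_len(w), each = h), h, w)
  mask <- matrix(TRUE, h, w)
  k <- scale_and_flatten(binomial_2d(2), alpha = 1)
  out <- masked_normalized_convolve(ramp, mask, k)
  interior <- erode_mask(mask, 2)
  expect_equal(out[interior], ramp[interior], tolerance = 1e-9)
})

test_that("an impulse moves the surface by at most its center-weight share", {
  h <- 21; w <- 21
  mask <- matrix(TRUE, h, w)
  base <- matrix(40, h, w)
  k <- scale_and_flatten(binomial_2d(2), alpha = 1)
  imp <- base; imp[11, 11] <- base[11, 11] + 100
  out0 <- masked_normalized_convolve(base, mask, k)
  out1 <- masked_normalized_convolve(imp, mask, k)
  bound <- 100 * max(k$coefficients) / sum(k$coefficients)
  expect_lte(max(abs(out1 - out0)), bound + 1e-9)
})

test_that("oversized kernels are rejected", {
  mask <- matrix(TRUE, 5, 5)
  ch <- matrix(1, 5, 5)
  expect_error(masked_normalized_convolve(ch, mask, binomial_2d(6)),
               "too large")
})

test_that("histogram median matches the sort oracle and its stated examples", {
  # 1x5 ROI, window 3: median of {2, 3, 100} at the center is 3
  mask <- matrix(FALSE, 3, 5); mask[2, ] <- TRUE
  ch <- matrix(0, 3, 5); ch[2, ] <- c(1, 2, 3, 100, 5)
  med <- fundusbf:::.masked_median(matrix(as.integer(ch), 3, 5), mask, 3L)
  expect_equal(med[2, 3], 3)

  # lower median on an even member count {10, 20} -> 10
  m2 <- matrix(FALSE, 1, 3); m2[1, 1:2] <- TRUE
  c2 <- matrix(as.integer(c(10, 20, 0)), 1, 3)
  expect_equal(fundusbf:::.masked_median(c2, m2, 3L)[1, 1], 10)

  set.seed(5)
  for (i in 1:10) {
    mask <- random_mask(14, 14)
    ch <- matrix(round(runif(196, 0, 255)), 14, 14)
    for (win in c(3, 5)) {
      got <- fundusbf:::.masked_median(matrix(as.integer(ch), 14, 14),
                                       mask, as.integer(win))
      expect_equal(got, oracle_masked_median(ch, mask, win))
    }
  }
  expect_error(masked_median_surface(ch, mask, window = 4), "odd")
})

test_that("median surface runs in the same framework (3x3 smoothing, masked)", {
  set.seed(9)
  mask <- random_mask(16, 16, p = 0.7)
  ch <- matrix(round(runif(256, 0, 255)), 16, 16); ch[!mask] <- 0
  bb <- masked_median_surface(ch, mask, window = 5)
  med <- oracle_masked_median(ch, mask, 5)
  expect_equal(bb, {
    s <- masked_average_3x3(med, mask)
    attr(s, "kernel_descriptor") <- attr(bb, "kernel_descriptor")
    s
  })
  expect_equal(attr(bb, "kernel_descriptor")$family, "median")
})
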