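test_that("motion_error computes Euclidean distances and bounded relative error", {
  a <- motion_trace(c(0, 1, 2), c(0, 2, -1), reference_index = 1)
  expect_equal(motion_error(a, a)$distances_mm, c(0, 0, 0))

  b <- motion_trace(c(0, 2, 3), c(0, 3, 0), reference_index = 1)
  me <- motion_error(b, a)
  expect_equal(me$distances_mm[2:3], c(sqrt(2), sqrt(2)))
  # relative error averages over interleaves with |truth| >= 0.5 mm only
  truth_mag <- c(0, sqrt(5), sqrt(5))
  expect_equal(me$relative_pct, 100 * mean(sqrt(2) / truth_mag[2:3]))

  expect_error(motion_error(a, motion_trace(0, 0)), "equal length")

  still <- motion_trace(c(0, 0.1), c(0, 0.1), reference_index = 1)
  expect_true(is.nan(motion_error(still, motion_trace(c(0, 0), c(0, 0)))$relative_pct))
})

test_that("snr_cnr implements the ROI formulas and guards degenerate input", {
  n <- 40
  img <- matrix(0, n, n)
  blood <- make_ellipse_mask(n, c(10, 10), c(4, 4))
  myo <- make_ellipse_mask(n, c(30, 10), c(4, 4))
  noise <- make_ellipse_mask(n, c(20, 32), c(5, 5))
  img[blood$grid == 1] <- 40
  img[myo$grid == 1] <- 20
  set.seed(3)
  img[noise$grid == 1] <- 5 + rnorm(sum(noise$grid))   # positive: sd survives Mod()
  s_noise <- sd(img[noise$grid == 1])
  out <- snr_cnr(img, blood, myo, noise)
  expect_equal(out$snr, 40 / s_noise)
  expect_equal(out$cnr, 20 / s_noise)

  # cnr = snr_blood - snr_myo algebraic identity on arbitrary images
  set.seed(9)
  img2 <- matrix(runif(n * n), n, n)
  o2 <- snr_cnr(img2, blood, myo, noise)
  o_myo <- snr_cnr(img2, myo, blood, noise)   # swap to read myo "snr"
  expect_equal(o2$cnr, o2$snr - o_myo$snr, tolerance = 1e-12)

  # equal intensities in both ROIs: zero CNR
  img3 <- matrix(1, n, n)
  img3[noise$grid == 1] <- rnorm(sum(noise$grid))
  expect_equal(snr_cnr(img3, blood, myo, noise)$cnr, 0)

  expect_error(snr_cnr(img, blood, blood, noise), "disjoint")
  expect_error(snr_cnr(matrix(1, n, n), blood, myo, noise), "degenerate")
})

# straight synthetic vessel: a horizontal bright band with configurable edge
# ramp, plus its centerline
band_vessel <- function(n = 64, width = 5, ramp = 0, value = 1) {
  img <- matrix(0, n, n)
  centre <- n / 2
  for (r in 1:n) {
    dist <- abs(r - centre) - width / 2
    img[r, ] <- if (dist <= -ramp / 2) value
    else if (dist >= ramp / 2) 0
    else value * (0.5 - dist / ramp)
  }
  list(img = img, centerline = cbind(x = 5:(n - 5), y = rep(centre, n - 9)))
}

# circular Gaussian blur with a wrap-centred kernel (no net shift)
blur <- function(img, sigma) {
  if (sigma == 0) return(img)
  n <- nrow(img)
  d <- pmin(0:(n - 1), n - (0:(n - 1)))
  k <- exp(-d^2 / (2 * sigma^2))
  k <- matrix(k, n, 1) %*% matrix(k, 1, n)
  Re(stats::fft(stats::fft(img) * stats::fft(k / sum(k)), inverse = TRUE)) / n^2
}

test_that("vessel sharpness: ideal edges 100%, 2-px linear ramp 50%", {
  v <- band_vessel(ramp = 0)
  vs <- vessel_sharpness(v$img, v$centerline, pixel_mm = 1)
  expect_equal(vs, 100)

  v2 <- band_vessel(width = 6, ramp = 2)
  vs2 <- vessel_sharpness(v2$img, v2$centerline, pixel_mm = 1)
  expect_equal(vs2, 50, tolerance = 0.02)
})

test_that("vessel sharpness decreases monotonically with blur", {
  v <- band_vessel(width = 6)
  vs <- vapply(c(0, 1, 2), function(s)
    vessel_sharpness(blur(v$img, s), v$centerline, pixel_mm = 1), numeric(1))
  expect_true(all(diff(vs) < 0))
})

test_that("measure_diameter reports FWHM widths with expected behaviour", {
  p <- make_phantom(128, 1.5, seed = 5)
  d <- measure_diameter(p$image, p$vessel$centerline, p$pixel_mm)
  expect_lt(abs(d - 3), 1.5)            # within one pixel of 3 mm

  # scale invariance
  d2 <- measure_diameter(5 * p$image, p$vessel$centerline, p$pixel_mm)
  expect_equal(d, d2, tolerance = 1e-12)

  # blur widens the FWHM
  expect_gte(measure_diameter(blur(p$image, 1.5), p$vessel$centerline,
                              p$pixel_mm), d)
})

test_that("sharpness and diameter are invariant to joint translation", {
  p <- make_phantom(128, 1.5, seed = 5)
  t <- c(0.4, 0.8)
  # exact (Fourier) shift: probes the metric's own interpolation, without the
  # low-pass a bilinear resampling would add to near-pixel-sharp edges
  img_t <- fourier_shift(p$image, t[1], t[2])
  cl_t <- p$vessel$centerline
  cl_t[, 1] <- cl_t[, 1] + t[1]
  cl_t[, 2] <- cl_t[, 2] + t[2]
  vs0 <- vessel_sharpness(p$image, p$vessel$centerline, p$pixel_mm)
  vs1 <- vessel_sharpness(img_t, cl_t, p$pixel_mm)
  expect_lt(abs(vs1 - vs0) / vs0, 0.02)
  d0 <- measure_diameter(p$image, p$vessel$centerline, p$pixel_mm)
  d1 <- measure_diameter(img_t, cl_t, p$pixel_mm)
  expect_lt(abs(d1 - d0) / d0, 0.02)
})

test_that("nav_agreement recovers correlation and regression slope", {
  set.seed(4)
  si <- cumsum(rnorm(30))
  out <- nav_agreement(si, si)
  expect_equal(out$cc, 1)
  expect_equal(out$slope, 1)

  # the navigator sees larger diaphragmatic excursions: slope = 0.37
  ref <- si / 0.37
  out2 <- nav_agreement(si, ref)
  expect_equal(out2$slope, 0.37, tolerance = 1e-12)
  expect_equal(out2$cc, 1)

  set.seed(5)
  a <- rnorm(100)
  b <- rnorm(100)
  expect_lt(abs(nav_agreement(a, b)$cc), 0.3)

  expect_error(nav_agreement(rep(1, 5), 1:5), "zero-variance")
  expect_error(nav_agreement(1:2, 1:2), "length")
})

test_that("protocol arithmetic reduces to the stated formulas", {
  out <- protocol_arithmetic(20, 20, 50)
  expect_equal(out$time_reduction_pct, 0)
  expect_equal(protocol_arithmetic(10, 20, 100)$efficiency_ratio, 1)
  expect_error(protocol_arithmetic(-1, 20, 50), "positive")
})

test_that("quality metrics are scale-invariant except SNR/CNR numerators", {
  p <- make_phantom(128, 1.5, seed = 5)
  vs0 <- vessel_sharpness(p$image, p$vessel$centerline, p$pixel_mm)
  vs1 <- vessel_sharpness(7 * p$image, p$vessel$centerline, p$pixel_mm)
  expect_equal(vs0, vs1, tolerance = 1e-12)
})
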