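test_that("phantom construction is deterministic and well-formed", {
  p1 <- make_phantom(96, 2, seed = 5)
  p2 <- make_phantom(96, 2, seed = 5)
  expect_identical(p1$image, p2$image)
  p3 <- make_phantom(96, 2, seed = 6)
  expect_false(identical(p1$image, p3$image))

  expect_true(all(p1$image >= 0 & p1$image <= 1))
  cl <- p1$vessel$centerline
  expect_true(all(cl >= 1 & cl <= 96))
  expect_error(make_phantom(32, 2), "at least 64")
})

test_that("the vessel is brighter than its surroundings", {
  p <- make_phantom(96, 2, seed = 5)
  cl <- p$vessel$centerline
  r0 <- p$vessel$diameter_mm / 2 / p$pixel_mm
  cc <- col(p$image)
  rr <- row(p$image)
  d2 <- matrix(Inf, 96, 96)
  for (i in seq_len(nrow(cl)))
    d2 <- pmin(d2, (cc - cl[i, 1])^2 + (rr - cl[i, 2])^2)
  inside <- d2 <= (0.7 * r0)^2
  nearby <- d2 > (2 * r0)^2 & d2 <= (4 * r0)^2
  expect_gt(mean(p$image[inside]), mean(p$image[nearby]) + 0.2)
})

test_that("rendered vessel diameter matches the registry (profile oracle)", {
  # independent full-width-half-maximum measurement across the centerline
  p <- make_phantom(128, 1.5, seed = 5)   # 1.5 mm px: vessel 2 px radius
  cl <- p$vessel$centerline
  i <- nrow(cl) %/% 2
  tg <- cl[i + 1, ] - cl[i - 1, ]
  nv <- c(-tg[2], tg[1]) / sqrt(sum(tg^2))
  offs <- seq(-6, 6, by = 0.1)
  prof <- vapply(offs, function(o) {
    x <- cl[i, 1] + o * nv[1]
    y <- cl[i, 2] + o * nv[2]
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    p$image[y0, x0] * (1 - fx) * (1 - fy) + p$image[y0, x0 + 1] * fx * (1 - fy) +
      p$image[y0 + 1, x0] * (1 - fx) * fy + p$image[y0 + 1, x0 + 1] * fx * fy
  }, numeric(1))
  bg <- min(prof)
  half <- bg + 0.5 * (max(prof) - bg)
  above <- range(which(prof >= half))
  fwhm_mm <- (offs[above[2]] - offs[above[1]]) * p$pixel_mm
  expect_lt(abs(fwhm_mm - p$vessel$diameter_mm), 1 * p$pixel_mm)
})

test_that("motion traces respect amplitude bounds and determinism", {
  tr <- make_motion_trace(24, 7, 5, seed = 12)
  mag <- sqrt(tr$dx_mm^2 + tr$dy_mm^2)
  expect_true(all(mag <= 7 + 1e-9))
  expect_gte(max(mag), 0.8 * 7)
  expect_equal(mag[tr$reference_index], 0)

  expect_identical(make_motion_trace(24, 7, 5, seed = 12)$dx_mm, tr$dx_mm)
  expect_false(identical(make_motion_trace(24, 7, 5, seed = 13)$dx_mm, tr$dx_mm))

  z <- make_motion_trace(10, 0, 5, seed = 1)
  expect_equal(max(abs(c(z$dx_mm, z$dy_mm))), 0)

  # changing the seed preserves the bounds
  for (s in 21:25) {
    m2 <- make_motion_trace(16, 5, 4, seed = s)
    expect_true(all(sqrt(m2$dx_mm^2 + m2$dy_mm^2) <= 5 + 1e-9))
  }
})

test_that("zero-trace zero-noise simulation equals the static forward model", {
  w <- small_world()
  st <- small_static()
  y <- nufft_forward(w$phantom$image, w$traj)
  expect_lt(max(Mod(st$data$samples[, , 1] - y)) / max(Mod(y)), 1e-12)
})

test_that("background noise level scales linearly with noise_sd", {
  w <- small_world()
  zt <- motion_trace(numeric(8), numeric(8), pixel_mm = w$traj$pixel_mm)
  base <- simulate_acquisition(w$phantom, w$traj, zt, noise_sd = 0)
  rmsy <- sqrt(mean(Mod(base$samples)^2))
  levels <- rmsy * c(0.005, 0.01, 0.02)
  bg_sd <- vapply(seq_along(levels), function(i) {
    d <- simulate_acquisition(w$phantom, w$traj, zt, noise_sd = levels[i],
                              seed = 100 + i)
    img <- Mod(gridding_reconstruct(d)$pixels)
    noise_px <- img[1:10, 1:10] - Mod(gridding_reconstruct(base)$pixels)[1:10, 1:10]
    sd(noise_px)
  }, numeric(1))
  fit <- lm(bg_sd ~ levels)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("simulation validates its inputs", {
  w <- small_world()
  tr_bad <- make_motion_trace(5, 7, 4, seed = 1)
  expect_error(simulate_acquisition(w$phantom, w$traj, tr_bad), "match")
  tr <- make_motion_trace(8, 7, 4, seed = 1)
  expect_error(
    simulate_acquisition(w$phantom, w$traj, tr,
                         confounder_trace = tr), "no confounder")
})

test_that("multi-coil simulation produces distinct channels with shared anatomy", {
  w <- small_world()
  zt <- motion_trace(numeric(8), numeric(8), pixel_mm = w$traj$pixel_mm)
  d <- simulate_acquisition(w$phantom, w$traj, zt, noise_sd = 0, coils = 3)
  expect_equal(dim(d$samples)[3], 3)
  expect_false(identical(d$samples[, , 1], d$samples[, , 2]))
  img <- gridding_reconstruct(d)
  expect_true(is.numeric(img$pixels))   # RSS magnitude
  expect_lt(nrmse(img$pixels, w$phantom$image), 0.08)
})
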