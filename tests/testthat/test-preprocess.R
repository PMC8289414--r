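# Movie conditioning: smoothing, masking, detrending, motion gating.

make_movie <- function(data_t_yx, frame_interval_s = 1, pixel_size_um = 1,
                       sat = 1e6) {
  d <- dim(data_t_yx)
  arr <- array(data_t_yx, dim = c(d[1L], 1L, d[2L], d[3L]))
  islet_movie(arr, frame_interval_s, pixel_size_um, sat)
}

test_that("the 5x5 averaging filter preserves constants and spreads an impulse", {
  const <- array(7, dim = c(2, 9, 9))
  out <- smooth_movie(make_movie(const))
  expect_equal(out$data, array(7, dim = c(2, 1, 9, 9)))

  imp <- array(0, dim = c(2, 11, 11))
  imp[, 6, 6] <- 25
  sm <- smooth_movie(make_movie(imp))
  frame <- matrix(sm$data[1, 1, , ], 11, 11)
  expect_equal(frame[4:8, 4:8], matrix(1, 5, 5))
  expect_equal(sum(frame), 25)
})

test_that("smoothing matches the naive double-loop mean at interior pixels", {
  set.seed(31)
  m <- matrix(runif(20 * 16), 20, 16)
  arr <- array(0, dim = c(2, 20, 16)); arr[1, , ] <- m; arr[2, , ] <- m
  sm <- smooth_movie(make_movie(arr))
  for (y in c(3, 10, 18)) for (x in c(3, 8, 14)) {
    expect_equal(sm$data[1, 1, y, x], naive_box_mean(m, y, x))
  }
})

test_that("smoothing conserves the mass of interior-supported signal", {
  set.seed(77)
  m <- matrix(0, 24, 24)
  m[7:18, 7:18] <- runif(144, 0, 10)  # support clear of the border
  arr <- array(0, dim = c(2, 24, 24)); arr[1, , ] <- m; arr[2, , ] <- m
  sm <- smooth_movie(make_movie(arr))
  expect_equal(sum(sm$data[1, 1, , ]), sum(m), tolerance = 1e-6 * sum(m))
})

test_that("smoothing rejects frames smaller than the kernel", {
  small <- array(1, dim = c(2, 4, 9))
  expect_error(smooth_movie(make_movie(small)), "smaller than")
})

test_that("masking excludes saturated and low-fluorescence pixels by rule", {
  arr <- array(50, dim = c(4, 6, 6))
  arr[3, 2, 2] <- 100          # touches saturation once
  arr[, 5, 5] <- 1             # dim pixel
  mv <- make_movie(arr, sat = 100)
  mask <- mask_islet(mv, min_mean_intensity = 10)
  lv <- attr(mask$reason, "levels")
  expect_false(mask$included[1, 2, 2])
  expect_equal(lv[mask$reason[1, 2, 2]], "saturated")
  expect_false(mask$included[1, 5, 5])
  expect_equal(lv[mask$reason[1, 5, 5]], "low_fluorescence")
  expect_true(mask$included[1, 3, 3])

  zero <- make_movie(array(0, dim = c(3, 5, 5)))
  expect_equal(sum(mask_islet(zero, min_mean_intensity = 1)$included), 0)
})

test_that("raising the intensity threshold never adds pixels", {
  set.seed(8)
  arr <- array(runif(5 * 8 * 8, 0, 100), dim = c(5, 8, 8))
  mv <- make_movie(arr, sat = 1e5)
  kept <- vapply(c(0, 20, 40, 60, 80), function(thr)
    sum(mask_islet(mv, min_mean_intensity = thr)$included), numeric(1))
  expect_true(all(diff(kept) <= 0))
  m1 <- mask_islet(mv, min_mean_intensity = 30)$included
  m2 <- mask_islet(mv, min_mean_intensity = 50)$included
  expect_true(all(m1[!m2] | !m2[!m2]))  # m2 subset of m1
  expect_true(all(!m2 | m1))
})

test_that("the default mask recovers the sensor-expressing footprint", {
  cfg <- simulation_config(seed = 12, n_cells = 60, n_frames = 40,
                           noise_sd = 3, sensor_fraction = 0.8)
  arch <- generate_architecture(cfg)
  gen <- generate_calcium_movie(arch, cfg)
  mask <- mask_islet(gen$movie)
  lab <- gen$truth$cell_pixels
  foot <- array(FALSE, dim = dim(mask$included))
  foot[1, , ] <- matrix(lab > 0 & gen$truth$active_cells[pmax(lab, 1)],
                        nrow(lab), ncol(lab))
  mismatch <- mean(mask$included != foot)
  expect_lt(mismatch, 0.05)
})

test_that("linear detrending removes lines exactly and is idempotent", {
  tt <- 1:50
  line <- 0.3 * tt + 2
  out <- detrend_linear(line)
  expect_equal(out, rep(2 + 0.3 * mean(tt), 50), tolerance = 1e-9)

  # sinusoid over integer periods, even about the sampling midpoint, is
  # orthogonal to the fitted line
  tt2 <- 1:100
  s <- cos(2 * pi * (tt2 - mean(tt2)) / 20)
  expect_equal(detrend_linear(s), s, tolerance = 1e-9)

  mix <- s + 0.05 * tt2 + 3
  rec <- detrend_linear(mix)
  expect_lt(sqrt(mean((rec - (s + mean(mix)))^2)), 1e-6)

  noisy <- rnorm(40) + 0.2 * (1:40)
  expect_equal(detrend_linear(detrend_linear(noisy)), detrend_linear(noisy),
               tolerance = 1e-9)
  expect_error(detrend_linear(c(1, 2)), "at least 3")
})

test_that("detrending a movie preserves per-pixel means", {
  set.seed(5)
  arr <- array(rnorm(10 * 6 * 6, 50), dim = c(10, 6, 6))
  mv <- make_movie(arr)
  out <- detrend_linear(mv)
  expect_equal(colMeans(matrix(out$data, 10)), colMeans(matrix(arr, 10)),
               tolerance = 1e-9)
})

test_that("the motion gate passes static movies and trims at half a cell width", {
  set.seed(3)
  base <- matrix(0, 40, 40)
  base[15:25, 10:30] <- 100  # bright structure to register on
  arr <- array(0, dim = c(60, 40, 40))
  for (t in 1:60) arr[t, , ] <- base + rnorm(1600, sd = 1)
  mv <- make_movie(arr, pixel_size_um = 1)
  expect_equal(assess_motion(mv, cell_width_um = 10)$status, "pass")

  # frames 51.. displaced by 6 px = 0.6 cell widths
  arr2 <- arr
  for (t in 51:60) arr2[t, , ] <- arr[t, c(7:40, 1:6), ]
  res <- assess_motion(make_movie(arr2, pixel_size_um = 1), cell_width_um = 10)
  expect_equal(res$status, "trim")
  expect_equal(res$t_end, 50)

  # constant sub-threshold shift (0.4 cell widths) passes
  arr3 <- arr
  for (t in 2:60) arr3[t, , ] <- arr[t, c(5:40, 1:4), ]
  expect_equal(assess_motion(make_movie(arr3, pixel_size_um = 1),
                             cell_width_um = 10)$status, "pass")

  # early large motion leaves too few frames -> reject
  arr4 <- arr
  for (t in 5:60) arr4[t, , ] <- arr[t, c(7:40, 1:6), ]
  expect_equal(assess_motion(make_movie(arr4, pixel_size_um = 1),
                             cell_width_um = 10)$status, "reject")
})
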