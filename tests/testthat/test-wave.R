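# Spectral peak, Fourier phase, time-lag conversion, wave speed and the
# eligibility gate.

test_that("the periodogram peak finds single and dominant tones", {
  fs <- 0.1; Tn <- 60  # 600 s at 0.1 Hz
  t <- (0:(Tn - 1)) / fs
  ps <- power_spectrum_peak(sin(2 * pi * 0.02 * t), fs)
  expect_equal(ps$f_peak_hz, 0.02, tolerance = (fs / Tn) / 0.02)

  two <- 2 * sin(2 * pi * 0.005 * t) + 1 * sin(2 * pi * 0.05 * t)
  Tn2 <- 200; t2 <- (0:(Tn2 - 1)) / fs
  two <- 2 * sin(2 * pi * 0.005 * t2) + sin(2 * pi * 0.05 * t2)
  expect_equal(power_spectrum_peak(two, fs)$f_peak_hz, 0.005,
               tolerance = (fs / Tn2) / 0.005)

  expect_error(power_spectrum_peak(rep(1, 64), fs), "constant")
  expect_error(power_spectrum_peak(rnorm(10), fs), "at least 32")
})

test_that("white-noise spectral peaks show no bin bias", {
  set.seed(21)
  fs <- 1; Tn <- 64
  ks <- replicate(50, {
    f <- power_spectrum_peak(rnorm(Tn), fs)$f_peak_hz
    round(f * Tn / fs)
  })
  # peaks spread over many bins rather than piling on one
  expect_gt(length(unique(ks)), 15)
  chi <- suppressWarnings(chisq.test(tabulate(ks, nbins = 32)))
  expect_gt(chi$p.value, 0.01)
})

test_that("a pure delay shifts the Fourier phase by -2*pi*f*tau", {
  fs <- 0.5; Tn <- 200
  t <- (0:(Tn - 1)) / fs
  f0 <- 0.02
  x <- sin(2 * pi * f0 * t)
  tau <- 6
  y <- sin(2 * pi * f0 * (t - tau))
  p1 <- phase_at_peak(x, f0, fs)
  p2 <- phase_at_peak(y, f0, fs)
  dphi <- Arg(exp(1i * (p2 - p1)))
  expect_equal(dphi, Arg(exp(1i * (-2 * pi * f0 * tau))),
               tolerance = 2 * pi / Tn)
  # anti-phase
  p3 <- phase_at_peak(-x, f0, fs)
  expect_equal(abs(Arg(exp(1i * (p3 - p1)))), pi, tolerance = 2 * pi / Tn)
})

test_that("phase differences are invariant to a common delay", {
  fs <- 0.5; Tn <- 200
  t <- (0:(Tn - 1)) / fs
  f0 <- 0.02
  x <- sin(2 * pi * f0 * t); y <- sin(2 * pi * f0 * (t - 4))
  d0 <- phase_at_peak(x, f0, fs) - phase_at_peak(y, f0, fs)
  xs <- sin(2 * pi * f0 * (t - 7)); ys <- sin(2 * pi * f0 * (t - 11))
  d1 <- phase_at_peak(xs, f0, fs) - phase_at_peak(ys, f0, fs)
  expect_equal(Arg(exp(1i * d0)), Arg(exp(1i * d1)), tolerance = 2 * pi / Tn)
})

test_that("the time-lag conversion matches both printed and standard forms", {
  expect_equal(time_lag(0.3, 0.3, 0.1, "as_printed"), 0)
  expect_equal(time_lag(0.3, 0.3, 0.005, "standard"), 0)
  # printed form evaluated directly: (1/f) * atan(phi1 - phi2)
  expect_equal(time_lag(pi / 4, 0, 0.1, "as_printed"),
               10 * atan(pi / 4), tolerance = 1e-12)
  expect_equal(time_lag(pi, 0, 0.005, "standard"), 100)
  # antisymmetry in both modes
  for (m in c("as_printed", "standard")) {
    expect_equal(time_lag(0.8, 0.2, 0.1, m), -time_lag(0.2, 0.8, 0.1, m))
  }
  expect_error(time_lag(1, 0, 0), "f must be")
})

test_that("the eligibility gate enforces the 80% rule strictly", {
  fake <- list(gradient_r2 = 0.9)
  expect_equal(eligibility_gate(0.79, fake), "low_coordination")
  expect_equal(eligibility_gate(0.80, fake), "low_coordination")
  expect_equal(eligibility_gate(0.95, fake), "eligible")
  expect_equal(eligibility_gate(0.95, list(gradient_r2 = 0.3)),
               "no_phase_transition")
})

test_that("a synthetic planar wave is eligible and recovers its speed", {
  cfg <- simulation_config(seed = 14, n_domains = 1, wave_speed_um_s = 30,
                           noise_sd = 10, frame_interval_s = 2,
                           n_frames = 300, slow_period_s = 60)
  arch <- generate_architecture(cfg)
  gen <- generate_calcium_movie(arch, cfg)
  sm <- smooth_movie(gen$movie)
  mask <- mask_islet(sm)
  dtm <- detrend_linear(sm)
  blocks <- block_traces(dtm, mask)
  frac <- largest_coordinated_fraction(merge_coordinated(blocks))
  pm <- analyze_wave(blocks, fs = 0.5, pixel_size_um = 1,
                     coordination_fraction = frac, mode = "standard")
  expect_equal(pm$eligibility, "eligible")
  expect_gt(pm$gradient_r2, 0.5)
  expect_equal(wave_speed(pm), 30, tolerance = 0.15)
})

test_that("a synchronous no-wave islet is gated out; random phases fail the fit", {
  cfg <- simulation_config(seed = 15, n_domains = 1, noise_sd = 10)
  arch <- generate_architecture(cfg)
  gen <- generate_calcium_movie(arch, cfg)
  sm <- smooth_movie(gen$movie)
  dtm <- detrend_linear(sm)
  blocks <- block_traces(dtm, mask_islet(sm))
  frac <- largest_coordinated_fraction(merge_coordinated(blocks))
  pm <- analyze_wave(blocks, fs = 0.2, pixel_size_um = 1,
                     coordination_fraction = frac)
  expect_equal(pm$eligibility, "no_phase_transition")
  expect_true(is.na(suppressMessages(wave_speed(pm))))

  # spatially random phases: gradient fit fails over seeds
  set.seed(16)
  fails <- replicate(20, {
    n <- 40; Tn <- 120; fs <- 0.5
    t <- (0:(Tn - 1)) / fs
    phis <- runif(n, -pi, pi)
    tr <- vapply(phis, function(p) sin(2 * pi * 0.02 * t + p) + rnorm(Tn, sd = 0.1),
                 numeric(Tn))
    info_blocks <- blocks_from_traces(tr)
    info_blocks$info$cy <- runif(n, 0, 100)
    info_blocks$info$cx <- runif(n, 0, 100)
    pm2 <- analyze_wave(info_blocks, fs = fs, pixel_size_um = 1,
                        coordination_fraction = 1, include_r = -1)
    pm2$gradient_r2 < 0.5
  })
  expect_gt(mean(fails), 0.95 - 1e-9)
})
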