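# Peak detection, activity classification and coordinated-area merging.

test_that("peak detection: flat traces yield nothing, bumps are found once", {
  expect_equal(nrow(detect_peaks(rep(3, 20))), 0L)

  # triangular bump of amplitude 10 on unit noise
  set.seed(1)
  tr <- rnorm(60)
  tr[25:35] <- tr[25:35] + c(seq(0, 10, length.out = 6), seq(8, 0, length.out = 5))
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 1L)
  # amplitude follows its definition (value minus 10th-percentile baseline)
  expect_equal(pk$amplitude, max(tr) - quantile(tr, 0.1, names = FALSE))
  expect_equal(pk$amplitude, 10, tolerance = 0.2)

  # two maxima two frames apart merge under the separation rule
  tr2 <- rep(0, 20)
  tr2[8] <- 10; tr2[10] <- 9
  pk2 <- detect_peaks(tr2 + rnorm(20, sd = 0.01))
  expect_equal(nrow(pk2), 1L)
  expect_equal(pk2$index, 8L)

  expect_error(detect_peaks(rep(1, 5)), "at least 10")
})

test_that("activity requires amplitude strictly above 1.5x background", {
  pk <- data.frame(index = 5L, time_s = 4, value = 3, amplitude = 3)
  expect_false(classify_active(pk, background = 2))   # exactly 1.5x
  expect_true(classify_active(pk, background = 1.4))  # above
  expect_true(classify_active(pk, background = 1.5))  # 2x
  expect_error(classify_active(pk, background = 0), "background")
  empty <- detect_peaks(rep(1, 15))
  expect_false(classify_active(empty, background = 1))
})

test_that("blocks sharing one trace form a single region; anti-phase halves form two", {
  set.seed(2)
  Tn <- 80
  base <- sin(2 * pi * (1:Tn) / 20)
  one <- matrix(rep(10 * base, 12), Tn, 12)
  map1 <- merge_coordinated(blocks_from_traces(one))
  expect_equal(max(map1$blocks$region_label), 1L)
  expect_equal(largest_coordinated_fraction(map1), 1)

  anti <- cbind(matrix(rep(10 * base, 6), Tn, 6),
                matrix(rep(-10 * base, 6), Tn, 6))
  map2 <- merge_coordinated(blocks_from_traces(anti))
  expect_equal(max(map2$blocks$region_label), 2L)
  expect_equal(largest_coordinated_fraction(map2), 0.5)
})

test_that("region partition equals brute-force union-find over the correlation matrix", {
  for (seed in 1:8) {
    set.seed(seed)
    Tn <- 60; n <- 20
    g <- matrix(rnorm(Tn * 4), Tn, 4)  # 4 latent generators
    mix <- g[, sample(4, n, replace = TRUE)] + matrix(rnorm(Tn * n, sd = 0.7), Tn, n)
    blocks <- blocks_from_traces(mix)
    map <- merge_coordinated(blocks, r_min = 0.7)
    R <- cor(mix)
    E <- R > 0.7; diag(E) <- FALSE
    oracle <- union_find_partition(E)
    # same partition up to relabeling
    expect_equal(length(unique(oracle)), max(map$blocks$region_label))
    for (lab in unique(oracle)) {
      members <- which(oracle == lab)
      expect_equal(length(unique(map$blocks$region_label[members])), 1L)
    }
  }
})

test_that("r_min extremes behave as set bounds", {
  set.seed(4)
  tr <- matrix(rnorm(50 * 8), 50, 8)
  blocks <- blocks_from_traces(tr)
  all_one <- merge_coordinated(blocks, r_min = -1)
  expect_equal(max(all_one$blocks$region_label), 1L)
  singletons <- merge_coordinated(blocks, r_min = 1)
  expect_equal(max(singletons$blocks$region_label), 8L)
})

test_that("largest coordinated fraction is non-increasing in r_min", {
  set.seed(6)
  Tn <- 60; n <- 15
  g <- matrix(rnorm(Tn * 3), Tn, 3)
  mix <- g[, sample(3, n, replace = TRUE)] + matrix(rnorm(Tn * n, sd = 1), Tn, n)
  blocks <- blocks_from_traces(mix)
  fr <- vapply(c(-0.5, 0, 0.3, 0.6, 0.9),
               function(r) largest_coordinated_fraction(
                 merge_coordinated(blocks, r_min = r)), numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("fractions are invariant under block order shuffling", {
  set.seed(9)
  Tn <- 60; n <- 12
  g <- matrix(rnorm(Tn * 2), Tn, 2)
  mix <- g[, rep(1:2, each = 6)] + matrix(rnorm(Tn * n, sd = 0.5), Tn, n)
  b1 <- blocks_from_traces(mix)
  perm <- sample(n)
  b2 <- blocks_from_traces(mix[, perm])
  m1 <- merge_coordinated(b1); m2 <- merge_coordinated(b2)
  expect_equal(largest_coordinated_fraction(m1), largest_coordinated_fraction(m2))
  expect_equal(sort(m1$region_pixels), sort(m2$region_pixels))
})

test_that("active fraction counts active over kept pixels by construction", {
  # 100 kept pixels with 30 strong oscillators among 70 noise-only traces
  set.seed(13)
  Tn <- 120
  osc <- 50 + 30 * sin(2 * pi * (1:Tn) / 24)
  traces <- matrix(50, Tn, 2)
  traces[, 2] <- osc
  assign <- matrix(1L, 10, 10)
  assign[sample(100, 30)] <- 2L
  mv <- movie_from_traces(traces, assign, 10, 10)
  mv$data <- mv$data + rnorm(length(mv$data))
  mask <- mask_islet(mv, min_mean_intensity = 25)
  expect_equal(sum(mask$included), 100)
  blocks <- block_traces(mv, mask, min_block_pixels = 13)
  map <- merge_coordinated(blocks)
  expect_equal(active_fraction(map), 0.30, tolerance = 0.02 / 0.30)
})

test_that("half-active construction gives exact fractions on clean data", {
  Tn <- 60
  osc <- 10 * sin(2 * pi * (1:Tn) / 15)
  active <- c(rep(TRUE, 4), rep(FALSE, 4))
  traces <- cbind(matrix(rep(osc, 4), Tn, 4) + matrix(rnorm(Tn * 4, sd = 0.01), Tn),
                  matrix(rnorm(Tn * 4, sd = 0.01), Tn, 4))
  blocks <- blocks_from_traces(traces, active = active,
                               n_active_pixels = rep(c(25L, 0L), each = 4))
  map <- merge_coordinated(blocks)
  expect_equal(active_fraction(map), 0.5)
  expect_equal(largest_coordinated_fraction(map), 1)
})
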