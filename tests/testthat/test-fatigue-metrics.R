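# EVL and CVL fatigue metrics, rainflow counting and band aggregation.

test_that("EVL closed forms: constant channel, single sample, duration doubling", {
  v0 <- 3e-4
  m <- bm_velocity_map(matrix(v0, 1, 100), 1000, 1000)
  r <- compute_evl(m, v0 = v0, bands = 1000, window_s = 1)
  expect_equal(unname(r$per_channel_levels), 10 * log10(100))
  expect_equal(unname(r$band_levels["1000"]), 10 * log10(100))

  m1 <- bm_velocity_map(matrix(v0, 1, 1), 1000, 1000)
  r1 <- compute_evl(m1, v0 = v0, bands = 1000, window_s = 1)
  expect_equal(unname(r1$per_channel_levels), 0)

  set.seed(2)
  x <- stats::rnorm(5000) * 1e-4
  md <- bm_velocity_map(matrix(c(x, x), 1, byrow = TRUE), 1000, 1000)
  ms <- bm_velocity_map(matrix(x, 1), 1000, 1000)
  rd <- compute_evl(md, v0 = v0, bands = 1000, window_s = 60)
  rs <- compute_evl(ms, v0 = v0, bands = 1000, window_s = 60)
  expect_equal(unname(rd$per_channel_levels - rs$per_channel_levels),
               10 * log10(2), tolerance = 1e-9)
})

test_that("EVL is monotone under pointwise amplification and flags silent channels", {
  set.seed(7)
  v <- matrix(stats::rnorm(3 * 500), 3, 500) * 1e-5
  m1 <- bm_velocity_map(v, c(800, 1000, 1250), 1000)
  m2 <- bm_velocity_map(v * 1.3, c(800, 1000, 1250), 1000)
  r1 <- compute_evl(m1, 1e-5, bands = 1000, window_s = 1)
  r2 <- compute_evl(m2, 1e-5, bands = 1000, window_s = 1)
  expect_true(all(r2$per_channel_levels >= r1$per_channel_levels))

  mz <- bm_velocity_map(rbind(v[1, ], 0), c(800, 1000), 1000)
  expect_warning(rz <- compute_evl(mz, 1e-5, bands = 1000, window_s = 1),
                 "all-zero")
  expect_identical(unname(rz$per_channel_levels[2]), -Inf)
})

test_that("rainflow matches the brute-force oracle on canonical sequences", {
  classic <- c(-2, 1, -3, 5, -1, 3, -4, 4, -2)
  expect_identical(cycle_key(rainflow_cycles(classic)),
                   cycle_key(oracle_rainflow(classic)))

  # ten full periods of a sinusoid: ~10 cycles at amplitude A, mean 0
  A <- 2.5
  s <- A * sin(2 * pi * 10 * seq(0, 1, by = 1 / 1000))
  cyc <- rainflow_cycles(s)
  expect_equal(sum(cyc$weight), 10, tolerance = 0.06)
  # the dominant cell holds ~10 cycles at (amplitude ~ A, mean ~ 0); only
  # the zero-start/zero-end boundary half-cycles fall elsewhere
  main <- abs(cyc$amplitude - A) < 0.05 * A & cyc$mean < 0.05 * A
  expect_gte(sum(cyc$weight[main]), 9)
  expect_lte(sum(cyc$weight[!main]), 1)

  expect_equal(nrow(rainflow_cycles(rep(1, 50))), 0)
})

test_that("rainflow counts equal the oracle across random Gaussian series", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(10:120, 1)
    s <- stats::rnorm(n)
    mine <- rainflow_cycles(s)
    orc <- oracle_rainflow(turning_points(s))
    expect_identical(cycle_key(mine), cycle_key(orc))
    # conservation: total counted weight bounded by number of reversals
    expect_lte(sum(mine$weight) * 2, length(turning_points(s)))
  }
})

test_that("rainflow histograms bin cycles with half-cycle weights", {
  s <- c(0, 1, 0.2, 0.8, -0.1, 1, 0)
  h <- rainflow_count(s, n_amp = 4, n_mean = 4, channel_cf = 1000)
  expect_equal(sum(h$counts), sum(rainflow_cycles(s)$weight))
  expect_true(all(diff(h$amp_edges) > 0))
  expect_true(all(diff(h$mean_edges) > 0))
  expect_equal(h$channel_cf, 1000)

  hz <- rainflow_count(rep(3, 10), 8, 8)
  expect_equal(sum(hz$counts), 0)
})

test_that("CVL closed forms: single cell, empty histogram, bilinear scaling", {
  # single full cycle between 1 and 3: amplitude 1, mean 2
  h <- rainflow_count(c(1, 3, 1), n_amp = 1, n_mean = 1, channel_cf = 1000)
  # two half-cycles (weight 1 total) in the single cell centred (0.5, 1)
  H <- miner_damage(h)
  expect_equal(H, 1 * 0.5 * 1, tolerance = 1e-12)
  r <- compute_cvl(list(h), h0 = H, bands = 1000, window_s = 1)
  expect_equal(unname(r$per_channel_levels), 0)

  he <- rainflow_count(rep(0, 10), 4, 4, channel_cf = 1000)
  expect_equal(miner_damage(he), 0)

  set.seed(9)
  v <- stats::rnorm(4000)
  H1 <- miner_damage(rainflow_count(v, 32, 32))
  H2 <- miner_damage(rainflow_count(2 * v, 32, 32))
  expect_equal(H2 / H1, 4, tolerance = 1e-9)
  expect_equal(10 * log10(H2^2 / H1^2), 12.04, tolerance = 0.2)
})

test_that("CVL and EVL rank tone responses of different amplitudes identically", {
  fs <- 48000
  bank <- build_filterbank(c(900, 1100))
  t <- seq(0, 0.2 - 1 / fs, by = 1 / fs)
  lv <- lapply(c(1e-7, 5e-7), function(A) {
    vs <- stapes_velocity(A * sin(2 * pi * 1000 * t), fs)
    map <- run_filterbank(vs, bank)
    list(evl = compute_evl(map, 1e-6, bands = 1000, window_s = 1),
         cvl = compute_cvl_map(map, 1e-6, bands = 1000, window_s = 1))
  })
  d_evl <- lv[[2]]$evl$band_levels - lv[[1]]$evl$band_levels
  d_cvl <- lv[[2]]$cvl$band_levels - lv[[1]]$cvl$band_levels
  expect_gt(unname(d_evl), 0)
  expect_gt(unname(d_cvl), 0)
})

test_that("metrics are invariant to time reversal of a stationary input", {
  set.seed(15)
  v <- matrix(stats::rnorm(2 * 3000), 2) * 1e-5
  m <- bm_velocity_map(v, c(900, 1100), 1000)
  mr <- bm_velocity_map(v[, ncol(v):1], c(900, 1100), 1000)
  e <- compute_evl(m, 1e-5, bands = 1000, window_s = 10)
  er <- compute_evl(mr, 1e-5, bands = 1000, window_s = 10)
  expect_equal(e$per_channel_levels, er$per_channel_levels, tolerance = 1e-12)
  c1 <- compute_cvl_map(m, 1e-5, bands = 1000, window_s = 10)
  c2 <- compute_cvl_map(mr, 1e-5, bands = 1000, window_s = 10)
  expect_equal(c1$per_channel_levels, c2$per_channel_levels, tolerance = 0.5)
})

test_that("octave band aggregation sums member powers with half-octave edges", {
  # one channel exactly at a band centre
  expect_equal(unname(aggregate_bands(4, 1000, bands = 1000)["1000"]), 4)
  # two equal-power members double the band power (+3.01 dB)
  p <- aggregate_bands(c(2, 2), c(900, 1100), bands = 1000)
  expect_equal(unname(p["1000"]), 4)
  expect_equal(unname(10 * log10(p["1000"]) - 10 * log10(2)), 10 * log10(2))
  # boundary: 1420 Hz is just above 1000*sqrt(2), so it belongs to 2 kHz
  p2 <- suppressWarnings(aggregate_bands(1, 1420, bands = c(1000, 2000)))
  expect_true(is.na(p2["1000"]))
  expect_equal(unname(p2["2000"]), 1)
  expect_warning(aggregate_bands(1, 300, bands = 16000), "no member")
})

test_that("reference calibration gives 0 dB for the reference condition", {
  fs <- 48000
  bank <- build_filterbank(erb_center_freqs(6, 500, 4000))
  ref <- calibrate_references(bank, NULL, fs = fs, window_s = 0.25)
  t <- seq(0, 0.25 - 1 / fs, by = 1 / fs)
  amp <- sqrt(2) * 10^(94 / 20) * 2e-5
  vs <- stapes_velocity(amp * sin(2 * pi * 1000 * t), fs)
  map <- run_filterbank(vs, bank)
  i <- which.min(abs(map$channel_cfs - ref$channel_cf))
  e <- compute_evl(map, ref$v0, bands = 1000, window_s = 0.25)
  expect_equal(unname(e$per_channel_levels[i]), 0, tolerance = 1e-9)
  cv <- compute_cvl_map(map, ref$h0, bands = 1000, window_s = 0.25)
  expect_equal(unname(cv$per_channel_levels[i]), 0, tolerance = 1e-9)
})
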