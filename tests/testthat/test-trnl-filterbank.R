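# TRNL filterbank: gammatone and low-pass cascades, broken-stick
# compression, parameter interpolation and BM velocity maps.

fs <- 48000

test_that("broken-stick nonlinearity evaluates its closed form", {
  a <- 850; b <- 0.03; cc <- 0.25
  expect_equal(broken_stick(0, a, b, cc), 0)
  expect_equal(broken_stick(1e-6, a, b, cc), 8.5e-4, tolerance = 1e-9)
  expect_equal(broken_stick(1e-3, a, b, cc), b * (1e-3)^cc, tolerance = 1e-9)
  # odd symmetry and continuity at the knee
  x <- seq(-1e-3, 1e-3, length.out = 1001)
  y <- broken_stick(x, a, b, cc)
  expect_equal(y, -rev(y))
  knee <- (b / a)^(1 / (1 - cc))
  expect_equal(broken_stick(knee * (1 + 1e-12), a, b, cc),
               broken_stick(knee * (1 - 1e-12), a, b, cc), tolerance = 1e-6)
})

test_that("gammatone cascade has unit gain at CF and strong off-band rejection", {
  x <- make_tone(800, fs, 0.3)
  y <- gammatone_cascade(x, 800, 450, 5, fs)
  expect_equal(steady_rms(y, fs) / steady_rms(x, fs), 1, tolerance = 0.01)

  expect_equal(gammatone_cascade(numeric(1000), 800, 450, 3, fs),
               numeric(1000))

  x4 <- make_tone(3200, fs, 0.3)
  y4 <- gammatone_cascade(x4, 800, 450, 3, fs)
  expect_lt(steady_rms(y4, fs) / steady_rms(x4, fs), 0.01)

  expect_error(gammatone_cascade(x, fs, 450, 3, fs), "Nyquist")
})

test_that("gammatone magnitude decays monotonically beyond two bandwidths", {
  gain <- function(f) Mod(cochfat:::.gammatone_gain(f, fs, 2000, 500, 3)) /
    Mod(cochfat:::.gammatone_gain(2000, fs, 2000, 500, 3))
  above <- vapply(seq(3000, 12000, by = 500), gain, numeric(1))
  below <- vapply(seq(1000, 100, by = -100), gain, numeric(1))
  expect_true(all(diff(above) < 0))
  expect_true(all(diff(below) < 0))
})

test_that("low-pass cascade has unit DC gain and Butterworth cutoff attenuation", {
  y <- lowpass_cascade(rep(0.7, fs / 2), 750, 7, fs)
  expect_equal(y[fs / 2], 0.7, tolerance = 1e-6)

  x <- make_tone(750, fs, 0.3)
  for (n in c(1, 3)) {
    yn <- lowpass_cascade(x, 750, n, fs)
    expect_equal(steady_rms(yn, fs) / steady_rms(x, fs), (1 / sqrt(2))^n,
                 tolerance = 0.01)
  }
  # far-band asymptote: >= 40 dB per stage at 10x cutoff (with margin)
  x10 <- make_tone(7500, fs, 0.3)
  y10 <- lowpass_cascade(x10, 750, 2, fs)
  expect_lt(20 * log10(steady_rms(y10, fs) / steady_rms(x10, fs)), -70)
  expect_error(lowpass_cascade(x, fs, 1, fs), "Nyquist")
})

test_that("anchor columns are returned verbatim and interpolation brackets", {
  bank <- build_filterbank(c(800, 12000))
  p800 <- bank[[1]]
  expect_equal(p800$g, 500); expect_equal(p800$a, 850)
  expect_equal(p800$b, 0.03); expect_equal(p800$k, 10)
  expect_equal(p800$cf_lin, 750); expect_equal(p800$bw_lin, 450)
  expect_equal(p800$cf_nl, 730); expect_equal(p800$lp_nl, 730)
  p12k <- bank[[2]]
  expect_equal(p12k$a, 22500); expect_equal(p12k$b, 0.07)
  expect_equal(p12k$k, 20)

  mid <- exp(mean(log(c(800, 5500))))
  pm <- build_filterbank(mid)[[1]]
  for (fl in c("g", "a", "b", "k", "cf_lin", "bw_lin")) {
    lo <- min(c(bank[[1]][[fl]], build_filterbank(5500)[[1]][[fl]]))
    hi <- max(c(bank[[1]][[fl]], build_filterbank(5500)[[1]][[fl]]))
    expect_gte(pm[[fl]], lo)
    expect_lte(pm[[fl]], hi)
  }
  expect_error(build_filterbank(numeric()), "empty")
  expect_error(build_filterbank(100), "outside")
})

test_that("channel output is the sum of its three path outputs", {
  p <- build_filterbank(2000)[[1]]
  set.seed(5)
  x <- stats::rnorm(4000) * 1e-5
  total <- trnl_channel(x, p, fs = fs)
  parts <- trnl_channel(x, p, paths = "linear", fs = fs) +
    trnl_channel(x, p, paths = "nonlinear", fs = fs) +
    trnl_channel(x, p, paths = "allpass", fs = fs)
  expect_equal(total, parts, tolerance = 1e-12)
  expect_equal(trnl_channel(numeric(1000), p, fs = fs), numeric(1000))
})

test_that("channel is linear at low level and compressive (slope c) in the b-branch", {
  p <- build_filterbank(800)[[1]]
  t <- seq(0, 0.25 - 1 / fs, by = 1 / fs)
  tone <- sin(2 * pi * p$cf_nl * t)
  rms_out <- function(amp, paths) {
    y <- trnl_channel(amp * tone, p, paths = paths, fs = fs)
    steady_rms(y, fs)
  }
  # low level, whole channel: halving input halves output
  lo <- rms_out(2e-8, c("linear", "nonlinear", "allpass"))
  hi <- rms_out(4e-8, c("linear", "nonlinear", "allpass"))
  expect_equal(hi / lo, 2, tolerance = 0.01)
  # b-branch, isolated nonlinear path: dB/dB slope ~ c = 0.25
  amps <- 10^seq(-4, -2, length.out = 5)
  outs <- vapply(amps, rms_out, numeric(1), paths = "nonlinear")
  slope <- stats::coef(stats::lm(20 * log10(outs) ~ I(20 * log10(amps))))[2]
  expect_equal(unname(slope), 0.25, tolerance = 0.03)
})

test_that("filterbank maps are tonotopic: rows peak at tones near their own CF", {
  bank <- small_bank(8, 500, 8000)
  cfs <- vapply(bank, `[[`, numeric(1), "cf")
  t <- seq(0, 0.25 - 1 / fs, by = 1 / fs)
  resp <- sapply(cfs, function(f) {        # columns: tones at channel CFs
    vs <- stapes_velocity(1e-7 * sin(2 * pi * f * t), fs)
    map <- run_filterbank(vs, bank)
    rowSums(map$velocities[, -(1:round(0.05 * fs))]^2)
  })
  best_tone <- apply(resp, 1, which.max)
  # best frequency sits at most one grid step from the nominal CF (the
  # low-pass cutoff at CF shifts it slightly downward)
  expect_true(all(abs(best_tone - seq_along(cfs)) <= 1))
})

test_that("zero input yields a zero map and channel order is ascending CF", {
  bank <- small_bank(5)
  vs <- stapes_velocity(numeric(2000), fs)
  map <- run_filterbank(vs, bank)
  expect_true(all(map$velocities == 0))
  expect_true(all(diff(map$channel_cfs) > 0))
  expect_equal(dim(map$velocities), c(5, 2000))
})

test_that("parameter validation rejects invalid channels", {
  expect_error(trnl_channel_params(1000, 900, 300, 900, 10, 950, 300, 950,
                                   100, 0.05, 1.2, 1), "exponent")
  expect_error(trnl_channel_params(-1, 900, 300, 900, 10, 950, 300, 950,
                                   100, 0.05, 0.3, 1), "positive")
})
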