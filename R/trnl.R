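# Triple-path nonlinear (TRNL) cochlear filterbank.
#
# Each tonotopic channel models BM velocity at one cochlear site as the sum
# of three parallel paths driven by stapes velocity:
#   linear:     g * GT^n_lin(cf_lin, bw_lin) -> LP^n(lp_lin)
#   nonlinear:  GT^n_nl(cf_nl, bw_nl) -> broken-stick -> GT^n_nl -> LP^n(lp_nl)
#   all-pass:   k * x  (broadband low-gain path)
# Gammatone cascades are all-pole resonator sections normalised post hoc so
# the whole cascade has exactly unit gain at its centre frequency; low-pass
# stages are second-order Butterworth (unit DC gain).

#' TRNL channel parameter set
#'
#' One column of the chinchilla parameter table: linear-path bandpass
#' (`cf_lin`, `bw_lin`), low-pass cutoff `lp_lin` and gain `g`;
#' nonlinear-path bandpass (`cf_nl`, `bw_nl`), low-pass cutoff `lp_nl` and
#' broken-stick parameters `a`, `b`, `c`; broadband all-pass gain `k`;
#' cascade orders `n_gt_lin`, `n_lp_lin`, `n_gt_nl`, `n_lp_nl`. `cf` is the
#' channel's nominal (tonotopic) centre frequency used for map labelling
#' and octave-band assignment.
#'
#' @param cf nominal channel CF, Hz.
#' @param cf_lin,bw_lin,lp_lin,g linear-path parameters.
#' @param cf_nl,bw_nl,lp_nl,a,b,c nonlinear-path parameters (0 < c < 1).
#' @param k all-pass path gain.
#' @param n_gt_lin,n_lp_lin,n_gt_nl,n_lp_nl cascade orders (>= 1).
#' @return object of class `trnl_channel_params`.
#' @export
trnl_channel_params <- function(cf, cf_lin, bw_lin, lp_lin, g,
                                cf_nl, bw_nl, lp_nl, a, b, c, k,
                                n_gt_lin = 5, n_lp_lin = 7,
                                n_gt_nl = 3, n_lp_nl = 4) {
  freqs <- c(cf, cf_lin, bw_lin, lp_lin, cf_nl, bw_nl, lp_nl)
  if (any(freqs <= 0)) stop("TRNL frequencies and bandwidths must be positive")
  if (c <= 0 || c >= 1) stop("compression exponent c must lie in (0, 1)")
  if (any(c(n_gt_lin, n_lp_lin, n_gt_nl, n_lp_nl) < 1))
    stop("cascade orders must be >= 1")
  if (any(c(g, a, b, k) < 0)) stop("gains must be non-negative")
  structure(list(cf = cf, cf_lin = cf_lin, bw_lin = bw_lin, lp_lin = lp_lin,
                 g = g, cf_nl = cf_nl, bw_nl = bw_nl, lp_nl = lp_nl,
                 a = a, b = b, c = c, k = k,
                 n_gt_lin = n_gt_lin, n_lp_lin = n_lp_lin,
                 n_gt_nl = n_gt_nl, n_lp_nl = n_lp_nl),
            class = "trnl_channel_params")
}

# effective real-filter gain of the complex one-pole gammatone cascade:
# for a real input, y = 2*Re{cascade}, so G(w) = H(w) + conj(H(-w)) with
# H(w) = (1 / (1 - p e^{-iw}))^n, p = rho e^{i theta}
.gammatone_gain <- function(f, fs, cf, bw, n) {
  w <- 2 * pi * f / fs
  p <- exp(-pi * bw / fs) * exp(1i * 2 * pi * cf / fs)
  H <- function(w) (1 / (1 - p * exp(-1i * w)))^n
  H(w) + Conj(H(-w))
}

#' Gammatone bandpass cascade
#'
#' `n` identical complex one-pole resonator sections at centre frequency
#' `cf` with nominal per-stage 3-dB bandwidth `bw` (the standard
#' complex-valued all-pole gammatone realisation, which has symmetric
#' skirts about CF), with the whole cascade normalised analytically to
#' unit magnitude gain at `cf`.
#'
#' @param x input signal (numeric vector).
#' @param cf centre frequency, Hz (< Nyquist).
#' @param bw nominal 3-dB bandwidth per section, Hz.
#' @param n number of cascaded sections (>= 1).
#' @param fs sampling rate, Hz.
#' @return filtered signal, same length as `x`.
#' @export
gammatone_cascade <- function(x, cf, bw, n, fs) {
  if (cf >= fs / 2) stop("gammatone cf must be below the Nyquist frequency")
  if (n < 1) stop("cascade order must be >= 1")
  rho <- exp(-pi * bw / fs)
  th <- 2 * pi * cf / fs
  y <- gammatone_core_cpp(as.numeric(x), rho, th, as.integer(n))
  y / Mod(.gammatone_gain(cf, fs, cf, bw, n))
}

#' Second-order Butterworth low-pass cascade
#'
#' `n` identical second-order Butterworth sections with cutoff `fc`; the
#' cascade has exactly unit DC gain and magnitude `(1/sqrt(2))^n` at `fc`.
#'
#' @param x input signal.
#' @param fc cutoff frequency, Hz (< Nyquist).
#' @param n number of sections (>= 1).
#' @param fs sampling rate, Hz.
#' @return filtered signal, same length as `x`.
#' @export
lowpass_cascade <- function(x, fc, n, fs) {
  if (fc >= fs / 2) stop("low-pass cutoff must be below the Nyquist frequency")
  if (n < 1) stop("cascade order must be >= 1")
  bt <- signal::butter(2, fc / (fs / 2), type = "low")
  y <- x
  for (i in seq_len(n)) y <- as.numeric(signal::filter(bt, y))
  y
}

#' Broken-stick compressive nonlinearity
#'
#' `y = sign(x) * min(a*|x|, b*|x|^c)`: linear (slope `a`) at low levels,
#' compressive (growth exponent `c`) above the knee
#' `|x| = (b/a)^(1/(1-c))`. Odd-symmetric and continuous.
#'
#' @param x input signal.
#' @param a linear-branch gain (> 0).
#' @param b compressive-branch gain (> 0).
#' @param c compression exponent in (0, 1).
#' @return transformed signal.
#' @export
broken_stick <- function(x, a, b, c) {
  if (a <= 0 || b <= 0) stop("a and b must be positive")
  if (c <= 0 || c >= 1) stop("c must lie in (0, 1)")
  ax <- abs(x)
  sign(x) * pmin(a * ax, b * ax^c)
}

#' Run one TRNL channel
#'
#' Sum of the three parallel paths applied to a stapes-velocity series.
#' `paths` restricts the computation to a subset (e.g. the isolated
#' nonlinear path for compression diagnostics).
#'
#' @param vs a [stapes_velocity()] (or numeric vector with `fs` given).
#' @param p a [trnl_channel_params()].
#' @param paths subset of `c("linear", "nonlinear", "allpass")`.
#' @param fs sampling rate, required when `vs` is a bare numeric vector.
#' @return BM velocity signal (numeric), same length as the input.
#' @export
trnl_channel <- function(vs, p, paths = c("linear", "nonlinear", "allpass"),
                         fs = NULL) {
  if (inherits(vs, "stapes_velocity")) {
    x <- vs$samples; fs <- vs$sample_rate
  } else {
    if (is.null(fs)) stop("supply `fs` for a bare numeric input")
    x <- as.numeric(vs)
  }
  paths <- match.arg(paths, several.ok = TRUE)
  y <- numeric(length(x))
  if ("linear" %in% paths) {
    yl <- gammatone_cascade(x, p$cf_lin, p$bw_lin, p$n_gt_lin, fs)
    yl <- lowpass_cascade(yl, p$lp_lin, p$n_lp_lin, fs)
    y <- y + p$g * yl
  }
  if ("nonlinear" %in% paths) {
    yn <- gammatone_cascade(x, p$cf_nl, p$bw_nl, p$n_gt_nl, fs)
    yn <- broken_stick(yn, p$a, p$b, p$c)
    yn <- gammatone_cascade(yn, p$cf_nl, p$bw_nl, p$n_gt_nl, fs)
    yn <- lowpass_cascade(yn, p$lp_nl, p$n_lp_nl, fs)
    y <- y + yn
  }
  if ("allpass" %in% paths) y <- y + p$k * x
  y
}

#' ERB-rate scale (Glasberg-Moore)
#'
#' @param f frequency in Hz.
#' @return ERB-rate (cams).
#' @export
erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' Inverse ERB-rate scale
#' @param e ERB-rate (cams).
#' @return frequency in Hz.
#' @export
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' ERB-spaced centre frequencies
#'
#' `n` channel CFs placed uniformly on the ERB-rate scale between `fmin`
#' and `fmax` (inclusive), ascending.
#'
#' @param n number of channels.
#' @param fmin,fmax band edges in Hz.
#' @return numeric vector of CFs.
#' @export
erb_center_freqs <- function(n = 40, fmin = 250, fmax = 16000) {
  stopifnot(n >= 1, fmin > 0, fmax > fmin)
  cfs <- erb_rate_inv(seq(erb_rate(fmin), erb_rate(fmax), length.out = n))
  cfs[1] <- fmin                 # pin endpoints against round-trip float error
  cfs[n] <- fmax
  cfs
}

#' Load the chinchilla TRNL anchor parameter table
#'
#' Seven published anchor columns (800 Hz to 14 kHz) of chinchilla TRNL
#' parameters: linear/nonlinear bandpass CFs and bandwidths, low-pass
#' cutoffs, path gains g, a, b, k, compression exponent c and cascade
#' orders.
#'
#' @param path YAML file; defaults to the packaged table.
#' @return data.frame with one row per anchor frequency.
#' @export
load_trnl_anchors <- function(path = system.file("extdata",
                                                 "trnl_chinchilla.yaml",
                                                 package = "cochfat")) {
  cfg <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(cfg$trnl_anchors, as.data.frame))
  df[order(df$freq), , drop = FALSE]
}

#' Build an ERB-spaced TRNL filterbank
#'
#' Interpolates each anchor parameter linearly in log frequency at the
#' requested channel CFs. Outside the anchor span, dimensionless
#' parameters (gains g, a, b, k and exponent c) are clamped to the nearest
#' anchor while frequency-valued parameters (bandpass CFs, bandwidths and
#' low-pass cutoffs) scale proportionally with the requested CF, so that
#' channels beyond the anchor span stay tuned to their own tonotopic
#' place. Cascade orders are constant across the table and taken verbatim.
#'
#' @param channel_cfs requested channel CFs in Hz (ascending not required;
#'   the returned bank is sorted ascending).
#' @param anchors anchor table from [load_trnl_anchors()].
#' @param cf_range admissible CF band (default 250 Hz to 16 kHz).
#' @return list of [trnl_channel_params()], ascending CF.
#' @export
build_filterbank <- function(channel_cfs, anchors = load_trnl_anchors(),
                             cf_range = c(250, 16000)) {
  if (length(channel_cfs) == 0) stop("empty channel CF list")
  if (any(channel_cfs < cf_range[1] | channel_cfs > cf_range[2]))
    stop("requested CFs outside the configured band [",
         cf_range[1], ", ", cf_range[2], "] Hz")
  channel_cfs <- sort(channel_cfs)
  lx <- log(anchors$freq)
  freq_fields <- c("cf_lin", "bw_lin", "lp_lin", "cf_nl", "bw_nl", "lp_nl")
  gain_fields <- c("g", "a", "b", "c", "k")
  lapply(channel_cfs, function(cf) {
    lq <- min(max(log(cf), lx[1]), lx[length(lx)])  # clamp to anchor span
    scale <- exp(log(cf) - lq)                      # != 1 only outside span
    vals <- c(
      vapply(freq_fields, function(fl)
        stats::approx(lx, anchors[[fl]], xout = lq)$y * scale, numeric(1)),
      vapply(gain_fields, function(fl)
        stats::approx(lx, anchors[[fl]], xout = lq)$y, numeric(1)))
    trnl_channel_params(
      cf = cf,
      cf_lin = vals[["cf_lin"]], bw_lin = vals[["bw_lin"]],
      lp_lin = vals[["lp_lin"]], g = vals[["g"]],
      cf_nl = vals[["cf_nl"]], bw_nl = vals[["bw_nl"]],
      lp_nl = vals[["lp_nl"]],
      a = vals[["a"]], b = vals[["b"]], c = vals[["c"]], k = vals[["k"]],
      n_gt_lin = anchors$n_gt_lin[1], n_lp_lin = anchors$n_lp_lin[1],
      n_gt_nl = anchors$n_gt_nl[1], n_lp_nl = anchors$n_lp_nl[1]
    )
  })
}

#' Basilar-membrane velocity map
#'
#' @param velocities channels x time matrix of BM velocities (m/s).
#' @param channel_cfs per-row channel CFs, Hz (ascending).
#' @param sample_rate Hz.
#' @return object of class `bm_velocity_map`.
#' @export
bm_velocity_map <- function(velocities, channel_cfs, sample_rate) {
  velocities <- as.matrix(velocities)
  if (nrow(velocities) != length(channel_cfs))
    stop("row count must equal the number of channel CFs")
  if (!all(is.finite(velocities))) stop("map entries must be finite")
  structure(list(velocities = velocities,
                 channel_cfs = as.numeric(channel_cfs),
                 sample_rate = as.numeric(sample_rate)),
            class = "bm_velocity_map")
}

#' @export
print.bm_velocity_map <- function(x, ...) {
  cat(sprintf("<bm_velocity_map> %d channels (%.0f-%.0f Hz) x %d samples @ %g Hz\n",
              nrow(x$velocities), min(x$channel_cfs), max(x$channel_cfs),
              ncol(x$velocities), x$sample_rate))
  invisible(x)
}

#' Run a TRNL filterbank over a stapes-velocity series
#'
#' @param vs a [stapes_velocity()].
#' @param bank list of [trnl_channel_params()] (from [build_filterbank()]).
#' @return a [bm_velocity_map()]; row i is channel i's BM velocity,
#'   channels ascending in CF.
#' @export
run_filterbank <- function(vs, bank) {
  if (length(bank) == 0) stop("empty filterbank")
  cfs <- vapply(bank, `[[`, numeric(1), "cf")
  ord <- order(cfs)
  v <- t(vapply(bank[ord], function(p) trnl_channel(vs, p),
                numeric(length(vs$samples))))
  bm_velocity_map(v, cfs[ord], vs$sample_rate)
}

#' Analytic-signal envelope
#'
#' FFT-based Hilbert envelope with optional moving-average smoothing.
#'
#' @param x real signal.
#' @param fs sampling rate, Hz.
#' @param smooth_ms moving-average window in ms (0 = no smoothing).
#' @return non-negative envelope, same length as `x`.
#' @export
signal_envelope <- function(x, fs, smooth_ms = 0) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::fft(X * h, inverse = TRUE) / n)
  if (smooth_ms > 0) {
    w <- max(1L, round(smooth_ms / 1000 * fs))
    env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
    env[is.na(env)] <- 0
  }
  env
}

#' Effective response duration (envelope FWHM)
#'
#' Full width at half maximum of the smoothed Hilbert envelope, in
#' seconds. Smoothing suppresses the one-sample feedthrough of the
#' broadband all-pass path so the measured width reflects the channel's
#' narrowband ringing; when the channel CF is supplied the window spans
#' four carrier periods (envelope resolution proportional to the carrier,
#' the usual convention), otherwise a fixed `smooth_ms` is used.
#'
#' @param x channel response signal.
#' @param fs sampling rate, Hz.
#' @param cf channel centre frequency, Hz (preferred; sets the smoothing
#'   window to four periods).
#' @param smooth_ms fixed envelope smoothing window in ms, used when `cf`
#'   is not given.
#' @return FWHM in seconds.
#' @export
response_duration <- function(x, fs, cf = NULL, smooth_ms = 0.5) {
  if (!is.null(cf)) smooth_ms <- 4000 / cf
  env <- signal_envelope(x, fs, smooth_ms = smooth_ms)
  above <- env >= max(env) / 2
  sum(above) / fs
}
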