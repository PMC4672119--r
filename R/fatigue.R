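# EVL and CVL fatigue metrics of basilar-membrane velocity maps.
#
# EVL (equal velocity level) treats the per-channel velocity history as
# S-N-curve loading: L_i = 10*log10(sum_j V(i,j)^2 / V0^2). CVL (complex
# velocity level) applies Miner's rule to rainflow-counted velocity cycles:
# damage H_i = sum over histogram cells of count * amplitude * mean, and
# L_i = 10*log10(H_i^2 / H0^2). Band levels sum the member-channel powers
# before the log.

OCTAVE_CENTERS <- c(500, 1000, 2000, 4000, 8000, 16000)

#' Turning points of a series
#'
#' Local extrema (reversals) including the first and last sample; runs of
#' equal values are collapsed first.
#'
#' @param x numeric vector (length >= 2).
#' @return numeric vector of reversal values.
#' @export
turning_points <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("series must have at least 2 samples")
  x <- x[c(TRUE, diff(x) != 0)]          # collapse plateaus
  if (length(x) < 3) return(x)
  d <- diff(x)
  keep <- c(TRUE, d[-1] * d[-length(d)] < 0, TRUE)
  x[keep]
}

#' Rainflow cycle extraction
#'
#' Four-point rainflow counting on the turning points of a load series,
#' with the residual counted as half-cycles (weight 0.5). Each cycle is
#' characterised by its amplitude (half the peak-valley range) and the
#' absolute mean of the pair.
#'
#' @param series numeric load series (length >= 2).
#' @return data.frame with columns `amplitude`, `mean`, `weight`.
#' @export
rainflow_cycles <- function(series) {
  tp <- turning_points(series)
  m <- rainflow_cycles_cpp(tp)
  as.data.frame(m)
}

#' Rainflow amplitude-mean histogram
#'
#' Bins rainflow cycles of one BM-velocity channel into an
#' `n_amp` x `n_mean` grid. Axes span `[0, max observed]` for amplitude and
#' absolute mean respectively; cycle counts accumulate cycle weights (half
#' cycles contribute 0.5). A constant series yields an all-zero histogram.
#'
#' @param series one channel of a BM velocity map (numeric).
#' @param n_amp,n_mean number of amplitude and mean bins (>= 1).
#' @param channel_cf channel centre frequency (Hz), carried as metadata.
#' @return object of class `rainflow_histogram` with fields `amp_edges`,
#'   `mean_edges`, `counts` (n_amp x n_mean matrix), `channel_cf`.
#' @export
rainflow_count <- function(series, n_amp = 32, n_mean = 32, channel_cf = NA) {
  stopifnot(n_amp >= 1, n_mean >= 1)
  cyc <- rainflow_cycles(series)
  amax <- if (nrow(cyc)) max(cyc$amplitude) else 0
  mmax <- if (nrow(cyc)) max(cyc$mean) else 0
  # degenerate axes (no cycles, or all means exactly zero) get a unit span
  amp_edges <- seq(0, if (amax > 0) amax else 1, length.out = n_amp + 1)
  mean_edges <- seq(0, if (mmax > 0) mmax else 1, length.out = n_mean + 1)
  counts <- matrix(0, n_amp, n_mean)
  if (nrow(cyc)) {
    ia <- pmin(pmax(findInterval(cyc$amplitude, amp_edges,
                                 rightmost.closed = TRUE), 1L), n_amp)
    im <- pmin(pmax(findInterval(cyc$mean, mean_edges,
                                 rightmost.closed = TRUE), 1L), n_mean)
    for (r in seq_len(nrow(cyc)))
      counts[ia[r], im[r]] <- counts[ia[r], im[r]] + cyc$weight[r]
  }
  structure(list(amp_edges = amp_edges, mean_edges = mean_edges,
                 counts = counts, channel_cf = channel_cf),
            class = "rainflow_histogram")
}

#' Miner-rule cumulative damage of a rainflow histogram
#'
#' `H = sum over cells of count * amplitude_center * mean_center`.
#'
#' @param hist a [rainflow_histogram()].
#' @return scalar damage H (>= 0).
#' @export
miner_damage <- function(hist) {
  ac <- (hist$amp_edges[-1] + hist$amp_edges[-length(hist$amp_edges)]) / 2
  mc <- (hist$mean_edges[-1] + hist$mean_edges[-length(hist$mean_edges)]) / 2
  sum(hist$counts * outer(ac, mc))
}

#' Fatigue metric result
#'
#' @param per_channel_levels dB per ERB channel.
#' @param band_levels named dB vector per octave band (names = centre Hz).
#' @param reference reference value used (V0 or H0).
#' @param window_seconds analysis window length, s.
#' @param metric "EVL" or "CVL".
#' @return object of class `fatigue_metric_result`.
#' @export
fatigue_metric_result <- function(per_channel_levels, band_levels,
                                  reference, window_seconds, metric) {
  structure(list(per_channel_levels = per_channel_levels,
                 band_levels = band_levels, reference = reference,
                 window_seconds = window_seconds, metric = metric),
            class = "fatigue_metric_result")
}

#' @export
print.fatigue_metric_result <- function(x, ...) {
  cat(sprintf("<fatigue_metric_result> %s, %d channels, window %g s, reference %.4g\n",
              x$metric, length(x$per_channel_levels), x$window_seconds,
              x$reference))
  print(round(x$band_levels, 2))
  invisible(x)
}

#' Aggregate per-channel powers into octave bands
#'
#' A channel belongs to the band centred at `c` iff its CF lies in
#' `[c/sqrt(2), c*sqrt(2))`. Band power is the sum of member channel
#' powers (linear domain, before any log). Bands with no member channel
#' are flagged `NA` with a warning.
#'
#' @param per_channel linear (power-domain) per-channel values.
#' @param channel_cfs channel centre frequencies, Hz.
#' @param bands octave band centres, Hz.
#' @return named numeric vector of band powers.
#' @export
aggregate_bands <- function(per_channel, channel_cfs,
                            bands = OCTAVE_CENTERS) {
  if (length(bands) == 0) stop("bands must be nonempty")
  stopifnot(length(per_channel) == length(channel_cfs))
  out <- vapply(bands, function(ctr) {
    member <- channel_cfs >= ctr / sqrt(2) & channel_cfs < ctr * sqrt(2)
    if (!any(member)) return(NA_real_)
    sum(per_channel[member])
  }, numeric(1))
  names(out) <- as.character(bands)
  if (anyNA(out))
    warning("octave band(s) with no member channels: ",
            paste(bands[is.na(out)], collapse = ", "), " Hz")
  out
}

# split 1..n into analysis windows of window_s seconds: all full windows,
# or the whole series as one window when it is shorter than window_s
.window_index <- function(n, fs, window_s) {
  wlen <- floor(window_s * fs)
  if (wlen >= n || wlen < 1) return(list(seq_len(n)))
  k <- n %/% wlen
  lapply(seq_len(k), function(i) ((i - 1) * wlen + 1):(i * wlen))
}

.db_mean <- function(levels) {
  # arithmetic mean of window levels; -Inf propagates
  if (any(!is.finite(levels))) return(-Inf)
  mean(levels)
}

#' Equal velocity level (EVL)
#'
#' Per-channel level `L_i = 10*log10(sum_j V(i,j)^2 / v0^2)` and octave
#' band level `L_I = 10*log10(sum_{i in I} sum_j V(i,j)^2 / v0^2)`,
#' computed per analysis window and aggregated as the arithmetic mean of
#' window levels.
#'
#' @param map a [bm_velocity_map()].
#' @param v0 reference velocity (> 0); see [calibrate_references()].
#' @param bands octave band centres, Hz.
#' @param window_s analysis window, s (default 40).
#' @return a [fatigue_metric_result()].
#' @export
compute_evl <- function(map, v0 = 1, bands = OCTAVE_CENTERS, window_s = 40) {
  stopifnot(v0 > 0, window_s > 0)
  wins <- .window_index(ncol(map$velocities), map$sample_rate, window_s)
  nch <- nrow(map$velocities)
  chan_lv <- matrix(NA_real_, length(wins), nch)
  band_lv <- matrix(NA_real_, length(wins), length(bands))
  for (w in seq_along(wins)) {
    pow <- rowSums(map$velocities[, wins[[w]], drop = FALSE]^2) / v0^2
    chan_lv[w, ] <- 10 * log10(pow)
    band_lv[w, ] <- suppressWarnings(
      10 * log10(aggregate_bands(pow, map$channel_cfs, bands)))
  }
  if (any(is.infinite(chan_lv)))
    warning("all-zero channel(s): EVL reported as -Inf")
  per_channel <- apply(chan_lv, 2, .db_mean)
  band <- apply(band_lv, 2, function(v) if (all(is.na(v))) NA_real_ else .db_mean(v))
  names(band) <- as.character(bands)
  fatigue_metric_result(per_channel, band, v0, window_s, "EVL")
}

#' Complex velocity level (CVL) from per-channel histograms
#'
#' Single-window form: given one rainflow histogram per channel, computes
#' Miner damage `H_i` and levels `L_i = 10*log10(H_i^2/h0^2)`,
#' `L_I = 10*log10(sum_{i in I} H_i^2/h0^2)`.
#'
#' @param histograms list of [rainflow_histogram()] (one per channel, with
#'   `channel_cf` set), ascending CF.
#' @param h0 reference damage (> 0); see [calibrate_references()].
#' @param bands octave band centres, Hz.
#' @param window_s analysis window the histograms were computed over, s
#'   (metadata).
#' @return a [fatigue_metric_result()].
#' @export
compute_cvl <- function(histograms, h0 = 1, bands = OCTAVE_CENTERS,
                        window_s = 40) {
  stopifnot(h0 > 0)
  H <- vapply(histograms, miner_damage, numeric(1))
  cfs <- vapply(histograms, `[[`, numeric(1), "channel_cf")
  if (all(H == 0)) warning("all histograms empty: CVL reported as -Inf")
  pow <- (H / h0)^2
  per_channel <- 10 * log10(pow)
  band <- suppressWarnings(10 * log10(aggregate_bands(pow, cfs, bands)))
  fatigue_metric_result(per_channel, band, h0, window_s, "CVL")
}

#' Complex velocity level (CVL) of a BM velocity map
#'
#' Windowed convenience wrapper: rainflow-counts each channel per analysis
#' window, computes [compute_cvl()] per window and aggregates by the
#' arithmetic mean of window levels.
#'
#' @param map a [bm_velocity_map()].
#' @param h0 reference damage (> 0).
#' @param bands octave band centres, Hz.
#' @param window_s analysis window, s.
#' @param n_amp,n_mean histogram resolution.
#' @return a [fatigue_metric_result()].
#' @export
compute_cvl_map <- function(map, h0 = 1, bands = OCTAVE_CENTERS,
                            window_s = 40, n_amp = 32, n_mean = 32) {
  wins <- .window_index(ncol(map$velocities), map$sample_rate, window_s)
  nch <- nrow(map$velocities)
  chan_lv <- matrix(NA_real_, length(wins), nch)
  band_lv <- matrix(NA_real_, length(wins), length(bands))
  for (w in seq_along(wins)) {
    hists <- lapply(seq_len(nch), function(i)
      rainflow_count(map$velocities[i, wins[[w]]], n_amp, n_mean,
                     channel_cf = map$channel_cfs[i]))
    res <- suppressWarnings(compute_cvl(hists, h0, bands, window_s))
    chan_lv[w, ] <- res$per_channel_levels
    band_lv[w, ] <- res$band_levels
  }
  per_channel <- apply(chan_lv, 2, .db_mean)
  band <- apply(band_lv, 2, function(v) if (all(is.na(v))) NA_real_ else .db_mean(v))
  names(band) <- as.character(bands)
  fatigue_metric_result(per_channel, band, h0, window_s, "CVL")
}

#' Reference values V0 and H0 from a calibrated 1 kHz tone
#'
#' Operational definition of the metric references: a calibrated pure tone
#' (default 1 kHz at 94 dB SPL) is run through the ear stages (optional)
#' and the TRNL channel whose CF is closest to the reference frequency,
#' over one analysis window. `v0` is defined so the EVL of the reference
#' condition is exactly 0 dB (`v0 = sqrt(sum V_ref^2)`), and `h0` is the
#' Miner damage of the reference response. Both are plain constants and
#' may instead be set directly; the choice shifts all levels by a common
#' offset and cancels in regressions.
#'
#' @param bank TRNL filterbank from [build_filterbank()].
#' @param ear optional ear configuration from [load_ear_config()]; `NULL`
#'   feeds the tone directly as stapes velocity.
#' @param fs sampling rate, Hz.
#' @param window_s analysis window length, s.
#' @param spl reference tone level, dB SPL.
#' @param freq reference frequency, Hz.
#' @param n_amp,n_mean histogram resolution for H0.
#' @return list with `v0`, `h0` and the reference channel's CF.
#' @export
calibrate_references <- function(bank, ear = NULL, fs = 48000, window_s = 1,
                                 spl = 94, freq = 1000,
                                 n_amp = 32, n_mean = 32) {
  cfs <- vapply(bank, `[[`, numeric(1), "cf")
  i <- which.min(abs(cfs - freq))
  t <- seq(0, window_s - 1 / fs, by = 1 / fs)
  amp <- sqrt(2) * 10^(spl / 20) * P_REF     # pressure amplitude, Pa
  tone <- pressure_waveform(amp * sin(2 * pi * freq * t), fs, "reference tone")
  vs <- if (is.null(ear)) {
    stapes_velocity(tone$samples, fs, label = tone$label)
  } else {
    cascade_ear(tone, ear$external, ear$middle, ear$footplate_area)
  }
  v <- trnl_channel(vs, bank[[i]])
  hist <- rainflow_count(v, n_amp, n_mean, channel_cf = cfs[i])
  list(v0 = sqrt(sum(v^2)), h0 = miner_damage(hist), channel_cf = cfs[i])
}
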