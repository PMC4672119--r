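# Calibrated pressure waveforms, dB SPL calibration and L_Aeq.

P_REF <- 2e-5  # reference pressure, Pa (20 micropascal)

#' Calibrated acoustic pressure waveform
#'
#' Container for a single-channel acoustic pressure time series in pascals.
#'
#' @param samples numeric vector of acoustic pressure samples (Pa).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param label free-text identifier carried through the pipeline.
#' @return an object of class `pressure_waveform` with fields `samples`,
#'   `sample_rate` and `label`.
#' @export
pressure_waveform <- function(samples, sample_rate, label = "") {
  samples <- as.numeric(samples)
  stopifnot(is.numeric(sample_rate), length(sample_rate) == 1, sample_rate > 0)
  if (!all(is.finite(samples))) stop("pressure samples must be finite")
  structure(list(samples = samples, sample_rate = as.numeric(sample_rate),
                 label = as.character(label)),
            class = "pressure_waveform")
}

#' @export
print.pressure_waveform <- function(x, ...) {
  cat(sprintf("<pressure_waveform> %s: %d samples @ %g Hz (%.3f s), RMS %.4g Pa\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              sqrt(mean(x$samples^2))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param wave a `pressure_waveform` or `stapes_velocity`.
#' @return duration in seconds.
#' @export
wave_duration <- function(wave) length(wave$samples) / wave$sample_rate

#' Full-scale calibration specification
#'
#' Maps digital full scale to sound pressure level: a full-scale (digital
#' amplitude 1.0) sine is declared to measure `fullscale_spl` dB SPL
#' (re 20 uPa). This is the microphone-calibration convention that works for
#' arbitrary recordings lacking measurement metadata.
#'
#' @param fullscale_spl dB SPL corresponding to a full-scale sine.
#' @return object of class `calibration_spec`.
#' @export
calibration_spec <- function(fullscale_spl = 94) {
  stopifnot(is.finite(fullscale_spl))
  structure(list(fullscale_spl = as.numeric(fullscale_spl),
                 reference_pressure = P_REF),
            class = "calibration_spec")
}

# Pa per unit digital amplitude: a unit-amplitude sine (digital RMS 1/sqrt(2))
# must have RMS pressure 10^(spl/20) * 20 uPa.
calibration_scale <- function(cal) {
  sqrt(2) * 10^(cal$fullscale_spl / 20) * cal$reference_pressure
}

#' Read a calibrated pressure waveform from a WAV file
#'
#' Digital samples are scaled to pascals using the full-scale-sine
#' convention of [calibration_spec()], then (optionally) resampled to the
#' pipeline's internal rate.
#'
#' @param path WAV file (PCM16/24 or float32); single channel unless
#'   `channel` selects one.
#' @param cal a [calibration_spec()].
#' @param channel 1-based channel index for multichannel files.
#' @param resample_to target sampling rate in Hz, or `NULL` to keep the
#'   file's rate. Defaults to 48 kHz, the internal rate used by the
#'   filterbank (comfortably above twice the highest channel CF).
#' @return a [pressure_waveform()].
#' @export
read_waveform <- function(path, cal = calibration_spec(), channel = NULL,
                          resample_to = 48000) {
  raw <- read_wav_raw(path, channel = channel)
  w <- pressure_waveform(raw$samples * calibration_scale(cal),
                         raw$sample_rate,
                         label = basename(path))
  if (!is.null(resample_to) && resample_to != w$sample_rate)
    w <- resample_waveform(w, resample_to)
  w
}

#' Write a calibrated pressure waveform to a WAV file
#'
#' Inverse of [read_waveform()]: pascals are divided by the calibration
#' scale before writing. Float32 output round-trips samples to single
#' precision.
#'
#' @param wave a [pressure_waveform()].
#' @param path output WAV path.
#' @param cal a [calibration_spec()] (must match the one used on read for a
#'   round trip).
#' @param format "float32" or "pcm16".
#' @return `path`, invisibly.
#' @export
write_waveform <- function(wave, path, cal = calibration_spec(),
                           format = "float32") {
  write_wav_raw(wave$samples / calibration_scale(cal), wave$sample_rate,
                path, format = format)
}

#' Resample a waveform to a new rate
#'
#' Polyphase resampling (via `signal::resample`) with a rational
#' approximation of the rate ratio.
#'
#' @param wave a [pressure_waveform()].
#' @param new_rate target rate in Hz.
#' @return resampled [pressure_waveform()].
#' @export
resample_waveform <- function(wave, new_rate) {
  if (new_rate == wave$sample_rate) return(wave)
  frac <- .rational_approx(new_rate / wave$sample_rate)
  y <- signal::resample(wave$samples, frac[1], frac[2])
  pressure_waveform(as.numeric(y), new_rate, wave$label)
}

# continued-fraction rational approximation p/q of x, q bounded
.rational_approx <- function(x, max_q = 1000) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > max_q) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    r <- 1 / (r - a)
  }
  c(p1, q1)
}

#' IEC A-weighting magnitude response
#'
#' Analytic pole formula of the standard A-curve, normalised to exactly
#' unit gain at 1 kHz.
#'
#' @param f frequencies in Hz (vector).
#' @return linear magnitude weights (0 at DC, 1 at 1 kHz).
#' @export
a_weighting <- function(f) {
  ra <- function(f) {
    f2 <- f^2
    (12194^2 * f2^2) /
      ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) * (f2 + 12194^2))
  }
  w <- ra(f) / ra(1000)
  w[f == 0] <- 0
  w
}

#' A-weighted equivalent continuous sound level (L_Aeq)
#'
#' Time-average A-weighted level over the full duration:
#' `10*log10(mean(A-weighted p^2) / (20 uPa)^2)`. The A-curve is applied in
#' the frequency domain from its analytic definition, so the result is
#' independent of any filter-design toolbox and (for band-limited content)
#' of the sampling rate.
#'
#' @param wave a [pressure_waveform()].
#' @return level in dBA; `-Inf` (with a warning) for silent input.
#' @export
compute_leq_a <- function(wave) {
  x <- wave$samples
  n <- length(x)
  if (n == 0) stop("empty waveform")
  if (all(x == 0)) {
    warning("silent input: L_Aeq is -Inf")
    return(-Inf)
  }
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * wave$sample_rate
  f <- pmin(f, wave$sample_rate - f)  # two-sided spectrum folds at Nyquist
  wsq <- a_weighting(f)^2
  msq <- sum(Mod(X)^2 * wsq) / n^2   # Parseval: mean of weighted p^2
  10 * log10(msq / P_REF^2)
}

#' Unweighted sound pressure level of a waveform
#'
#' `20*log10(p_rms / 20 uPa)`; convenience used by calibration checks and
#' the reference-tone definition of V0/H0.
#'
#' @param wave a [pressure_waveform()].
#' @return SPL in dB re 20 uPa.
#' @export
compute_spl <- function(wave) {
  rms <- sqrt(mean(wave$samples^2))
  if (rms == 0) return(-Inf)
  20 * log10(rms / P_REF)
}
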