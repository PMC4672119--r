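# Independent oracles used to cross-check the package implementations.

# Brute-force four-point rainflow counter: repeatedly scans the whole
# turning-point sequence from the left for the first removable inner pair
# (inner range <= both flanking ranges), records it as one full cycle and
# removes it; the final residual is counted pairwise as half-cycles.
# Deliberately O(n^2) and structurally different from the package's
# streaming stack implementation.
oracle_rainflow <- function(tp) {
  tp <- as.numeric(tp)
  amp <- c(); mn <- c(); wt <- c()
  repeat {
    n <- length(tp)
    if (n < 4) break
    found <- FALSE
    for (i in seq_len(n - 3)) {
      r1 <- abs(tp[i] - tp[i + 1])
      r2 <- abs(tp[i + 1] - tp[i + 2])
      r3 <- abs(tp[i + 2] - tp[i + 3])
      if (r2 <= r1 && r2 <= r3) {
        amp <- c(amp, r2 / 2)
        mn <- c(mn, abs((tp[i + 1] + tp[i + 2]) / 2))
        wt <- c(wt, 1)
        tp <- tp[-c(i + 1, i + 2)]
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  for (i in seq_len(max(0, length(tp) - 1))) {
    r <- abs(tp[i] - tp[i + 1])
    if (r > 0) {
      amp <- c(amp, r / 2)
      mn <- c(mn, abs((tp[i] + tp[i + 1]) / 2))
      wt <- c(wt, 0.5)
    }
  }
  data.frame(amplitude = amp %||% numeric(), mean = mn %||% numeric(),
             weight = wt %||% numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical string of a cycle multiset, for cell-for-cell comparison
cycle_key <- function(df) {
  if (nrow(df) == 0) return(character())
  sort(sprintf("%.10g|%.10g|%.3g", df$amplitude, df$mean, df$weight))
}

# closed-form normal-equations OLS with t-distribution p-value
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% b
  n <- length(y)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  se_slope <- sqrt(ss_res / (n - 2) / sum((x - mean(x))^2))
  tstat <- b[2] / se_slope
  list(intercept = b[1], slope = b[2],
       r_squared = 1 - ss_res / ss_tot,
       p_value = 2 * stats::pt(-abs(tstat), n - 2))
}

# pure tone helper (unit amplitude unless given)
make_tone <- function(freq, fs = 48000, dur = 0.3, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur - 1 / fs, by = 1 / fs))
}

# steady-state RMS, discarding the leading transient
steady_rms <- function(x, fs, skip_s = 0.05) {
  sqrt(mean(x[-seq_len(round(skip_s * fs))]^2))
}

# small ERB bank shared by several tests
small_bank <- function(n = 8, fmin = 400, fmax = 12000) {
  build_filterbank(erb_center_freqs(n, fmin, fmax))
}
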