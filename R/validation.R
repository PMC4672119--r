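# Hearing-loss indices, the packaged chinchilla exposure dataset and the
# single-variable regression used to relate fatigue metrics to hearing loss.

#' Load the chinchilla hair-cell-loss dataset
#'
#' Published 22-group chinchilla noise-exposure dataset: per exposure group
#' the A-weighted equivalent level of the 320-s exposure noise (dBA) and
#' the percentage outer and inner hair cell loss at the six one-octave
#' bands centred at 0.5, 1, 2, 4, 8 and 16 kHz. Per-group PTS/TTS values
#' were not published alongside and are not included. The packaged file is
#' integrity-checked (MD5) on load.
#'
#' @param path CSV file; defaults to the packaged copy.
#' @return data.frame with columns `group`, `laeq`, `ohc_<hz>` and
#'   `ihc_<hz>` for hz in 500...16000 (22 rows).
#' @export
load_hearing_loss_data <- function(path = system.file(
  "extdata", "chinchilla_hair_cell_loss.csv", package = "cochfat")) {
  expected_md5 <- "580581ea625c710f164d02a737d6f0bf"
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, expected_md5))
    stop("hair-cell-loss fixture checksum mismatch (got ", sum, ")")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 22) stop("fixture must contain exactly 22 exposure groups")
  pct <- df[, grepl("^(ohc|ihc)_", names(df))]
  if (any(pct < 0 | pct > 100)) stop("percent losses must lie in [0, 100]")
  df
}

#' Average an index over the 1, 2, 4 and 8 kHz octave bands
#'
#' The "1248" summary: arithmetic mean of the four band values, applied
#' identically to PTS, TTS, OHC loss and IHC loss.
#'
#' @param values numeric vector of per-band values. Either an unnamed
#'   vector of exactly four values (taken as 1, 2, 4, 8 kHz in order) or a
#'   vector named by band centre in Hz from which the four bands are
#'   extracted.
#' @return the averaged value.
#' @export
band_average_1248 <- function(values) {
  need <- c("1000", "2000", "4000", "8000")
  if (!is.null(names(values))) {
    if (!all(need %in% names(values)))
      stop("missing band(s): ", paste(setdiff(need, names(values)),
                                      collapse = ", "), " Hz")
    values <- values[need]
  } else if (length(values) != 4) {
    stop("supply exactly four band values (1, 2, 4, 8 kHz) or a named vector")
  }
  if (anyNA(values)) stop("missing band value")
  mean(as.numeric(values))
}

#' Single-variable linear regression
#'
#' Ordinary least squares `y = c0 + c1*x + e` with `r^2 = 1 - SS_res/SS_tot`
#' and a two-sided t-test p-value for the slope (n - 2 degrees of freedom).
#'
#' @param x predictor (metric values).
#' @param y response (hearing-loss values).
#' @return object of class `regression_result`: list with `intercept`,
#'   `slope`, `r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("degenerate design: x is constant")
  if (stats::sd(y) == 0) {
    # constant response: no explainable variance, slope indistinguishable
    # from zero
    return(structure(list(intercept = mean(y), slope = 0, r_squared = 0,
                          p_value = 1, n = length(x)),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # silence perfect-fit chatter
  p <- if (sm$sigma == 0) 0 else sm$coefficients["x", "Pr(>|t|)"]
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 p_value = p, n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> y = %.4g + %.4g x, r^2 = %.3f, p = %.3g, n = %d\n",
              x$intercept, x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Regress hearing-loss indices on fatigue metrics per band
#'
#' Joins a per-group metric table with the hearing-loss records on `group`
#' and fits one [linear_regression()] per requested band, pairing the
#' metric's band level with the index value at that band. Band `"1248"`
#' pairs the 1-8 kHz averages of both sides. Unmatched groups are listed
#' in a warning and excluded.
#'
#' @param metrics data.frame with columns `group`, `band_hz`, `level_db`
#'   (and optionally `metric` to disambiguate; filter beforehand).
#' @param records hearing-loss data from [load_hearing_loss_data()].
#' @param index one of "OHC", "IHC", "PTS", "TTS" (PTS/TTS require columns
#'   `pts_<hz>` / `tts_<hz>` in `records`, absent from the packaged data).
#' @param bands vector of band centres in Hz and/or the string "1248".
#' @return data.frame with columns `pair`, `band_hz`, `r2`, `p`, `n`.
#' @export
correlate_metrics <- function(metrics, records,
                              index = c("OHC", "IHC", "PTS", "TTS"),
                              bands = c(500, 1000, 2000, 4000, 8000, 16000)) {
  index <- match.arg(index)
  prefix <- tolower(index)
  unmatched <- setdiff(unique(metrics$group), records$group)
  if (length(unmatched))
    warning("groups without hearing-loss records excluded: ",
            paste(unmatched, collapse = ", "))
  metrics <- metrics[metrics$group %in% records$group, , drop = FALSE]
  centers <- c(500, 1000, 2000, 4000, 8000, 16000)

  rows <- lapply(bands, function(b) {
    if (identical(as.character(b), "1248")) {
      grp <- intersect(unique(metrics$group), records$group)
      x <- vapply(grp, function(g) {
        lv <- metrics[metrics$group == g & metrics$band_hz %in%
                        c(1000, 2000, 4000, 8000), "level_db"]
        mean(lv)
      }, numeric(1))
      y <- vapply(grp, function(g) {
        r <- records[records$group == g, ]
        band_average_1248(stats::setNames(
          as.numeric(r[paste0(prefix, "_", c(1000, 2000, 4000, 8000))]),
          c("1000", "2000", "4000", "8000")))
      }, numeric(1))
    } else {
      col <- paste0(prefix, "_", as.integer(b))
      if (!col %in% names(records))
        stop("index ", index, " has no values at ", b, " Hz in the records")
      sub <- metrics[metrics$band_hz == as.numeric(b), , drop = FALSE]
      grp <- intersect(sub$group, records$group)
      x <- vapply(grp, function(g)
        sub$level_db[sub$group == g][1], numeric(1))
      y <- vapply(grp, function(g)
        records[records$group == g, col], numeric(1))
    }
    fit <- linear_regression(x, y)
    data.frame(pair = paste0("L-", index), band_hz = as.character(b),
               r2 = fit$r_squared, p = fit$p_value, n = fit$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
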