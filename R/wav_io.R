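# Minimal RIFF/WAVE reader and writer.
#
# Supports the encodings found in field recordings: PCM 16-bit, PCM 24-bit
# and IEEE float32, mono or multichannel. Samples are exchanged as doubles
# normalised to [-1, 1] full scale (float data is taken verbatim).

#' Read a WAV file as normalised digital samples
#'
#' @param path path to a RIFF/WAVE file (PCM16, PCM24 or float32).
#' @param channel 1-based channel index to extract. Required when the file
#'   has more than one channel.
#' @return list with `samples` (double vector, full scale = 1), `sample_rate`
#'   (Hz), `n_channels`, `bits` and `format` ("pcm" or "float").
#' @keywords internal
read_wav_raw <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("cannot read WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2,
                               signed = FALSE, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2,
                               signed = FALSE, endian = "little")
      )
      # WAVE_FORMAT_EXTENSIBLE: true format is in the first two bytes of
      # the 16-byte SubFormat GUID at offset 24 of the fmt chunk
      if (fmt$audio_format == 65534L && size >= 26) {
        fmt$audio_format <- readBin(fmt_raw[25:26], "integer", 1, 2,
                                    signed = FALSE, endian = "little")
      }
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV file (missing fmt or data chunk): ", path)

  bytes_per <- fmt$bits %/% 8L
  n_frames <- length(data_raw) %/% (bytes_per * fmt$n_channels)
  x <- switch(
    as.character(fmt$audio_format),
    "1" = { # integer PCM
      if (fmt$bits == 16L) {
        as.numeric(readBin(data_raw, "integer",
                           n_frames * fmt$n_channels, 2,
                           signed = TRUE, endian = "little")) / 32768
      } else if (fmt$bits == 24L) {
        m <- matrix(as.integer(data_raw), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits)
    },
    "3" = { # IEEE float
      if (fmt$bits != 32L) stop("unsupported float bit depth: ", fmt$bits)
      readBin(data_raw, "double", n_frames * fmt$n_channels, 4,
              endian = "little")
    },
    stop("unsupported WAV audio format code: ", fmt$audio_format)
  )

  if (fmt$n_channels > 1L) {
    if (is.null(channel))
      stop("WAV file has ", fmt$n_channels,
           " channels; supply `channel` to select one")
    if (channel < 1L || channel > fmt$n_channels)
      stop("channel index out of range")
    x <- x[seq(channel, length(x), by = fmt$n_channels)]
  }
  list(samples = x, sample_rate = fmt$sample_rate,
       n_channels = fmt$n_channels, bits = fmt$bits,
       format = if (fmt$audio_format == 3L) "float" else "pcm")
}

#' Write normalised digital samples to a WAV file
#'
#' @param samples double vector, full scale = 1 (clipped for PCM output).
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param format "float32" (default, lossless for doubles within float
#'   precision) or "pcm16".
#' @keywords internal
write_wav_raw <- function(samples, sample_rate, path, format = "float32") {
  format <- match.arg(format, c("float32", "pcm16"))
  con <- file(path, "wb")
  on.exit(close(con))

  if (format == "float32") {
    bytes_per <- 4L; fmt_code <- 3L; bits <- 32L
    payload_n <- length(samples) * bytes_per
  } else {
    bytes_per <- 2L; fmt_code <- 1L; bits <- 16L
    payload_n <- length(samples) * bytes_per
  }
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_n), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * bytes_per), con, 4, endian = "little")
  writeBin(bytes_per, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_n), con, 4, endian = "little")
  if (format == "float32") {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  } else {
    v <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
    writeBin(v, con, 2, endian = "little")
  }
  invisible(path)
}
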