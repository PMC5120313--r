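#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader for mono PCM 16-bit and IEEE float 32-bit files
#' (the formats this package writes and the common interchange cases).
#' Files at other sampling rates can be resampled on input by linear
#' interpolation, adequate for the sub-50 Hz envelope content this package
#' analyses.
#'
#' @param path Path to a WAV file.
#' @param target_fs If non-`NULL`, resample to this rate.
#' @return A [waveform].
#' @export
read_wav <- function(path, target_fs = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        fs = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file: ", path)
  if (fmt$channels != 1L) stop("multichannel audio unsupported (mono only)")
  x <- if (fmt$audio_format == 1L && fmt$bits == 16L) {
    readBin(data, "integer", length(data) %/% 2L, size = 2,
            signed = TRUE, endian = "little") / 32767
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    readBin(data, "numeric", length(data) %/% 4L, size = 4, endian = "little")
  } else {
    stop("unsupported WAV encoding (need PCM16 or float32)")
  }
  w <- waveform(x, fmt$fs)
  if (!is.null(target_fs) && target_fs != fmt$fs) {
    n_out <- round(length(x) * target_fs / fmt$fs)
    t_out <- (0:(n_out - 1)) / target_fs
    y <- stats::approx((0:(length(x) - 1)) / fmt$fs, x, xout = t_out,
                       rule = 2)$y
    w <- waveform(y, target_fs)
  }
  w
}

#' Write a mono WAV file
#'
#' @param wave A [waveform] (samples are clipped to `[-1, 1]`).
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, bits = 16L) {
  stopifnot(inherits(wave, "waveform"), bits %in% c(16L, 32L))
  x <- pmin(pmax(wave$samples, -1), 1)
  n <- length(x)
  bytes_per <- bits %/% 8L
  data_sz <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_sz), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  fmt_code <- if (bits == 16L) 1L else 3L
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little") # mono
  writeBin(as.integer(wave$fs), con, size = 4, endian = "little")
  writeBin(as.integer(wave$fs * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_sz), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}
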