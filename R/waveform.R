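#' Sampled waveform
#'
#' Lightweight container for a mono sampled signal.
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz (positive scalar).
#' @return Object of class `"waveform"`: list with `samples` and `fs`.
#' @export
waveform <- function(samples, fs) {
  stopifnot(is.numeric(samples), length(samples) >= 1L,
            is.numeric(fs), length(fs) == 1L, fs > 0)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s), peak %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              max(abs(x$samples))))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

# Accept either a waveform or a bare numeric vector + fs in signal ops.
.wave_parts <- function(x, fs = NULL) {
  if (inherits(x, "waveform")) return(list(samples = x$samples, fs = x$fs))
  if (is.numeric(x)) {
    if (is.null(fs)) stop("fs must be supplied when x is a bare numeric vector")
    return(list(samples = as.numeric(x), fs = as.numeric(fs)))
  }
  stop("x must be a waveform or numeric vector")
}
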