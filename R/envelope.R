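#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Computes the discrete analytic signal `s(n) = s_r(n) + i s_h(n)` whose real
#' part is the input and whose imaginary part is its Hilbert transform, by the
#' one-sided spectrum method on the full signal.
#'
#' @param x A [waveform] or numeric vector.
#' @param fs Sampling rate in Hz (ignored if `x` is a waveform).
#' @return Complex vector, same length as the input; `Re()` equals the input
#'   exactly.
#' @examples
#' a <- analytic_signal(cos(2 * pi * 50 * (0:999) / 8000), fs = 8000)
#' @export
analytic_signal <- function(x, fs = NULL) {
  w <- .wave_parts(x, fs)
  s <- w$samples
  n <- length(s)
  if (n == 0L) stop("empty signal")
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    if (n > 2L) h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    if (n > 1L) h[2L:((n + 1L) / 2L)] <- 2
  }
  a <- stats::fft(stats::fft(s) * h, inverse = TRUE) / n
  # real part is the input in exact arithmetic; enforce the identity
  complex(real = s, imaginary = Im(a))
}

#' Hilbert envelope
#'
#' Magnitude of the analytic signal: the broadband amplitude envelope.
#'
#' @inheritParams analytic_signal
#' @return Nonnegative numeric vector, same length as the input.
#' @examples
#' env <- hilbert_envelope(sin(2 * pi * 440 * (0:7999) / 16000), fs = 16000)
#' @export
hilbert_envelope <- function(x, fs = NULL) {
  Mod(analytic_signal(x, fs))
}

#' Band-limited envelope oscillation
#'
#' Extracts one modulation band from the envelope with a zero-phase
#' third-order Butterworth bandpass. The filter is applied in the frequency
#' domain as the exact bilinear-transform Butterworth magnitude-squared
#' response (the steady-state equivalent of forward-backward filtering:
#' zero net group delay, effective sixth-order magnitude), with mirror
#' extension of the signal to suppress wrap-around. Direct recursive
#' filtering is unusable here: the bands of interest are a few Hz wide at a
#' 16 kHz rate, where IIR coefficient rounding makes filtfilt diverge.
#'
#' @param env Envelope signal (numeric vector or [waveform]).
#' @param band A [band], a canonical band name, or `c(f_lo, f_hi)` in Hz.
#' @param fs Sampling rate in Hz (ignored if `env` is a waveform).
#' @param order Butterworth order of one pass (default 3).
#' @return Numeric vector, same length as `env`.
#' @examples
#' t <- (0:15999) / 16000
#' osc <- bandpass_oscillation(1 + 0.5 * cos(2 * pi * 7 * t), "theta", fs = 16000)
#' @export
bandpass_oscillation <- function(env, band, fs = NULL, order = 3) {
  w <- .wave_parts(env, fs)
  b <- as_band(band)
  if (b$f_hi >= w$fs / 2) stop("band above Nyquist")
  x <- w$samples
  n <- length(x)
  if (n == 0L) stop("empty signal")
  xe <- c(x, rev(x)) # even extension: continuous at both ends
  m <- length(xe)
  f <- (0:(m - 1L)) / m
  omega <- pmin(f, 1 - f) * 2 * pi
  Om <- tan(omega / 2) # bilinear prewarped analog frequency
  Ol <- tan(pi * b$f_lo / w$fs)
  Ou <- tan(pi * b$f_hi / w$fs)
  r <- (Om^2 - Ol * Ou) / ((Ou - Ol) * Om)
  r[!is.finite(r)] <- Inf # DC: fully rejected
  H2 <- 1 / (1 + r^(2 * order))
  y <- Re(stats::fft(stats::fft(xe) * H2, inverse = TRUE)) / m
  y[seq_len(n)]
}

#' Instantaneous phase of an oscillation
#'
#' Phase angle of the analytic signal of a band-limited oscillation, wrapped
#' to `(-pi, pi]`.
#'
#' @param osc Numeric vector or [waveform]: a band-limited oscillation.
#' @param fs Sampling rate in Hz (unused in the computation; accepted for
#'   interface symmetry).
#' @return Numeric vector of phase values in `(-pi, pi]`.
#' @examples
#' phi <- instantaneous_phase(cos(2 * pi * 7 * (0:15999) / 16000))
#' @export
instantaneous_phase <- function(osc, fs = NULL) {
  v <- if (inherits(osc, "waveform")) osc$samples else as.numeric(osc)
  if (length(v) == 0L) stop("empty signal")
  if (all(v == 0)) stop("degenerate oscillation")
  Arg(analytic_signal(v, fs = 1))
}

#' Phase-quadrant labels
#'
#' Maps each phase value to one of the four quadrants
#' `[-pi, -pi/2) -> 1`, `[-pi/2, 0) -> 2`, `[0, pi/2) -> 3`, `[pi/2, pi] -> 4`.
#' Quadrants are half-open on the right except the last, so every phase in
#' `(-pi, pi]` gets exactly one label; `-pi` maps to 1 and `pi` to 4.
#'
#' @param phase Numeric vector of phase values in `[-pi, pi]`.
#' @return Integer vector of labels in `1:4`.
#' @examples
#' quadrant_labels(c(-pi, -1, 0.1, pi))
#' @export
quadrant_labels <- function(phase) {
  stopifnot(is.numeric(phase))
  findInterval(phase, c(-pi / 2, 0, pi / 2)) + 1L
}

#' Phase-quadrant crossing boundaries
#'
#' Sample indices at which the quadrant label changes (including the wrap
#' from quadrant 4 back to 1), plus the outer boundaries 0 and the signal
#' length. Indices are 0-based: boundary `n` separates samples `n-1` and `n`,
#' so every frame is the half-open interval between consecutive boundaries.
#'
#' @param phase Numeric vector of phase values (or precomputed labels via
#'   `labels`).
#' @param labels Optional integer labels from [quadrant_labels()].
#' @return Strictly increasing integer vector of 0-based boundary indices,
#'   always starting at 0 and ending at `length(phase)`.
#' @examples
#' phi <- instantaneous_phase(cos(2 * pi * 7 * (0:15999) / 16000))
#' head(quadrant_crossings(phi))
#' @export
quadrant_crossings <- function(phase, labels = NULL) {
  lab <- if (is.null(labels)) quadrant_labels(phase) else as.integer(labels)
  n <- length(lab)
  interior <- which(diff(lab) != 0L) # 0-based index of first sample in new quadrant
  sort(unique(c(0L, interior, n)))
}
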