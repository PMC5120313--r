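#' ERB-spaced filterbank energies of one frame
#'
#' The frame is Hamming-windowed, zero-padded to the next power of two
#' (at least 256), and its power spectrum integrated over `n_channels`
#' bands of equal width on the ERB-number scale
#' (`ERB(f) = 21.4 log10(1 + 0.00437 f)`) spanning `f_lo`-`f_hi` Hz.
#' The channel vector is scaled to unit Euclidean norm; an all-zero frame
#' keeps a zero spectrum.
#'
#' @param frame_samples Numeric vector: one frame of the waveform.
#' @param fs Sampling rate in Hz.
#' @param n_channels Number of ERB channels (default 33).
#' @param f_lo,f_hi Band span in Hz (defaults 100 and 7500).
#' @param min_len Minimum acceptable frame length in samples.
#' @return Numeric vector of length `n_channels` with attribute
#'   `center_freqs` (Hz); unit norm unless all-zero.
#' @examples
#' e <- erb_filterbank_energies(sin(2 * pi * 1000 * (0:399) / 16000), 16000)
#' @export
erb_filterbank_energies <- function(frame_samples, fs, n_channels = 33L,
                                    f_lo = 100, f_hi = 7500, min_len = 32L) {
  x <- as.numeric(frame_samples)
  if (length(x) < min_len) stop("frame shorter than minimum frame length")
  ed <- erb_design(fs, n_channels, f_lo, f_hi,
                   nfft = 2^ceiling(log2(max(length(x), 256L))))
  P <- frame_power_spectrum(x, ed$nfft)
  ch <- as.numeric(ed$M %*% P)
  nrm <- sqrt(sum(ch^2))
  if (nrm > 0) ch <- ch / nrm
  attr(ch, "center_freqs") <- ed$centers
  ch
}

# ERB number scale (Glasberg & Moore).
erb_number <- function(f) 21.4 * log10(1 + 0.00437 * f)
erb_number_inv <- function(e) (10^(e / 21.4) - 1) / 0.00437

# Binning matrix (channels x spectrum bins) for a given FFT size; cached per
# (fs, nfft, span) since frame lengths repeat heavily within a corpus.
erb_design <- local({
  cache <- new.env(parent = emptyenv())
  function(fs, n_channels, f_lo, f_hi, nfft) {
    key <- paste(fs, n_channels, f_lo, f_hi, nfft, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    edges <- erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi),
                                length.out = n_channels + 1L))
    freqs <- (0:(nfft %/% 2L)) * fs / nfft
    idx <- findInterval(freqs, edges, rightmost.closed = TRUE)
    M <- matrix(0, n_channels, length(freqs))
    keep <- idx >= 1L & idx <= n_channels
    M[cbind(idx[keep], which(keep))] <- 1
    out <- list(M = M, nfft = nfft,
                centers = erb_number_inv((erb_number(edges[-1]) +
                                          erb_number(edges[-length(edges)])) / 2))
    cache[[key]] <- out
    out
  }
})

frame_power_spectrum <- function(x, nfft) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  if (n == 1L) w <- 1
  xp <- c(x * w, numeric(nfft - n))
  Mod(stats::fft(xp)[1:(nfft %/% 2L + 1L)])^2
}

#' Cochlea-scaled spectral entropy of a segmentation
#'
#' Measures the information gain a segmentation extracts from a waveform:
#' each frame is reduced to a unit-norm 33-channel ERB spectrum, the
#' Euclidean distance between every pair of adjacent frames is computed,
#' and the mean distance is the CSE. Segmentations whose boundaries fall at
#' spectral change points score high; boundaries inside spectrally steady
#' stretches contribute near-zero distances and dilute the mean.
#'
#' @param x A [waveform] or numeric vector.
#' @param frames A [frame_set] (or an `nvfs` object) with at least 2 frames.
#' @param fs Sampling rate (ignored if `x` is a waveform).
#' @param ... Passed to [erb_filterbank_energies()].
#' @return Object of class `"cse"`: list with `value` (mean distance),
#'   `distances` (per adjacent pair, each in `[0, 2]`) and `n_frames`.
#' @examples
#' syl <- synth_cv(syllable_spec("p", "aa", seed = 2))
#' cse(syl$wave, nvfs(syl$wave))
#' @export
cse <- function(x, frames, fs = NULL, ...) {
  if (inherits(frames, "nvfs")) frames <- frames$frames
  stopifnot(inherits(frames, "frame_set"))
  if (nrow(frames) < 2L) stop("CSE undefined for fewer than 2 frames")
  w <- .wave_parts(x, if (is.null(fs)) 1 else fs)
  S <- do.call(cbind, lapply(seq_len(nrow(frames)), function(i) {
    seg <- w$samples[(frames$start[i] + 1L):frames$end[i]]
    as.numeric(erb_filterbank_energies(seg, w$fs, ...))
  }))
  dif <- S[, -1L, drop = FALSE] - S[, -ncol(S), drop = FALSE]
  d <- sqrt(colSums(dif^2))
  structure(list(value = mean(d), distances = d, n_frames = nrow(frames)),
            class = "cse")
}

#' @export
print.cse <- function(x, ...) {
  cat(sprintf("<cse> %.4f over %d frames (%d adjacent distances)\n",
              x$value, x$n_frames, length(x$distances)))
  invisible(x)
}

#' Scan band combinations for the CSE-maximizing nested reference
#'
#' Runs the nested segmentation for every ordered pair of distinct candidate
#' bands (primary, secondary), computes the CSE of each resulting frame set,
#' and ranks pairs by descending CSE. Pairs whose segmentation yields fewer
#' than 2 frames get `NA` and rank last.
#'
#' @param x A [waveform] or numeric vector.
#' @param fs Sampling rate (ignored if `x` is a waveform).
#' @param bands Named list of candidate [band]s (default [speech_bands()]).
#' @param alpha,beta,min_frame_ms As in [nvfs()].
#' @return Data frame with columns `primary`, `secondary`, `cse`, `rank`,
#'   sorted by rank.
#' @examples
#' syl <- synth_cv(syllable_spec("k", "ih", seed = 3))
#' head(band_scan(syl$wave))
#' @export
band_scan <- function(x, fs = NULL, bands = speech_bands(),
                      alpha = 0.32, beta = 0.8, min_frame_ms = 2) {
  w <- .wave_parts(x, fs)
  if (length(bands) < 2L) stop("need at least 2 candidate bands")
  env <- hilbert_envelope(w$samples, w$fs)
  if (all(env == 0)) stop("no envelope modulation")
  oscs <- lapply(bands, function(b) bandpass_oscillation(env, b, w$fs))
  nb <- names(bands)
  out <- expand.grid(primary = nb, secondary = nb,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[out$primary != out$secondary, , drop = FALSE]
  out$cse <- vapply(seq_len(nrow(out)), function(k) {
    fit <- nvfs_from_tracks(w$samples, w$fs,
                            oscs[[out$primary[k]]], oscs[[out$secondary[k]]],
                            bands[[out$primary[k]]], bands[[out$secondary[k]]],
                            alpha = alpha, beta = beta,
                            min_frame_ms = min_frame_ms)
    if (nrow(fit$frames) < 2L) NA_real_ else cse(w$samples, fit$frames, w$fs)$value
  }, numeric(1))
  out$rank <- rank(-out$cse, ties.method = "first", na.last = "keep")
  out$rank[is.na(out$rank)] <- seq(sum(!is.na(out$cse)) + 1L, nrow(out),
                                   length.out = sum(is.na(out$cse)))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}
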