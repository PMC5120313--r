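#' MFCC features over a (possibly variable-size) frame set
#'
#' Computes the standard 39-dimensional MFCC vector per frame: each frame is
#' Hamming-windowed, zero-padded to the next power of two (at least 256),
#' its power spectrum passed through 26 triangular mel filters spanning
#' 0 to `fs/2`, log-compressed (power floor 1e-10) and DCT-II transformed;
#' cepstra 0-12 are kept and first/second temporal derivatives are appended
#' by 2-frame linear regression over the frame sequence with edge
#' replication. Unequal frame durations are handled by the per-frame
#' zero-padding; derivatives run over frame index, not time.
#'
#' @param x A [waveform] or numeric vector.
#' @param frames A [frame_set] (or an `nvfs` object).
#' @param fs Sampling rate (ignored if `x` is a waveform).
#' @param n_filters Number of mel filters (default 26).
#' @param n_cep Cepstra kept per frame (default 13).
#' @param min_len Minimum frame length in samples.
#' @param time_aware_deltas If `TRUE`, the derivative regressions run
#'   against actual frame-center times (slope per 10 ms) instead of frame
#'   index; identical on a uniform 10 ms grid, better behaved when frame
#'   durations vary by an order of magnitude.
#' @return Numeric matrix, one row per frame, `3 * n_cep` columns named
#'   `c0..`, `d0..`, `a0..`; attribute `frame_times` holds frame centers in
#'   seconds.
#' @examples
#' syl <- synth_cv(syllable_spec("g", "aa", seed = 5))
#' f <- mfcc_for_frames(syl$wave, nvfs(syl$wave))
#' dim(f)
#' @export
mfcc_for_frames <- function(x, frames, fs = NULL, n_filters = 26L,
                            n_cep = 13L, min_len = 32L,
                            time_aware_deltas = FALSE) {
  if (inherits(frames, "nvfs")) frames <- frames$frames
  stopifnot(inherits(frames, "frame_set"))
  w <- .wave_parts(x, if (is.null(fs)) 1 else fs)
  nf <- nrow(frames)
  C <- matrix(0, nf, n_cep)
  for (i in seq_len(nf)) {
    seg <- w$samples[(frames$start[i] + 1L):frames$end[i]]
    if (length(seg) < min_len)
      stop(sprintf("frame %d shorter than minimum frame length", i))
    nfft <- 2^ceiling(log2(max(length(seg), 256L)))
    P <- frame_power_spectrum(seg, nfft)
    fb <- mel_design(w$fs, nfft, n_filters)
    logE <- log(pmax(as.numeric(fb %*% P), 1e-10))
    C[i, ] <- dct2(logE)[1:n_cep]
  }
  frame_times <- (frames$start + frames$end) / 2 / w$fs
  D <- delta_features(C, times = if (time_aware_deltas) frame_times else NULL)
  A <- delta_features(D, times = if (time_aware_deltas) frame_times else NULL)
  out <- cbind(C, D, A)
  colnames(out) <- c(paste0("c", 0:(n_cep - 1)), paste0("d", 0:(n_cep - 1)),
                     paste0("a", 0:(n_cep - 1)))
  attr(out, "frame_times") <- frame_times
  out
}

mel_of <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# Triangular mel filterbank matrix (filters x spectrum bins), cached.
mel_design <- local({
  cache <- new.env(parent = emptyenv())
  function(fs, nfft, n_filters) {
    key <- paste(fs, nfft, n_filters, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pts <- mel_inv(seq(0, mel_of(fs / 2), length.out = n_filters + 2L))
    freqs <- (0:(nfft %/% 2L)) * fs / nfft
    M <- matrix(0, n_filters, length(freqs))
    for (k in seq_len(n_filters)) {
      lo <- pts[k]; mid <- pts[k + 1L]; hi <- pts[k + 2L]
      up <- (freqs - lo) / (mid - lo)
      down <- (hi - freqs) / (hi - mid)
      M[k, ] <- pmax(0, pmin(up, down))
    }
    cache[[key]] <- M
    M
  }
})

# Orthogonality-free DCT-II with HTK-style sqrt(2/M) scaling.
dct2 <- function(v) {
  M <- length(v)
  k <- 0:(M - 1)
  vapply(k, function(kk)
    sqrt(2 / M) * sum(v * cos(pi * kk * ((1:M) - 0.5) / M)), numeric(1))
}

# Regression deltas with window 2 and edge replication. With `times` given,
# the regression runs against actual frame-center times and the slope is
# expressed per 10 ms, so on a uniform 10 ms grid the two forms coincide;
# the time-aware form is what unequal frame durations call for.
delta_features <- function(C, N = 2L, times = NULL) {
  nf <- nrow(C)
  pad <- rbind(C[rep(1L, N), , drop = FALSE], C,
               C[rep(nf, N), , drop = FALSE])
  D <- matrix(0, nf, ncol(C))
  if (is.null(times)) {
    denom <- 2 * sum((1:N)^2)
    for (t in seq_len(nf)) {
      acc <- 0
      for (th in 1:N) {
        acc <- acc + th * (pad[t + N + th, ] - pad[t + N - th, ])
      }
      D[t, ] <- acc / denom
    }
  } else {
    # replicate edge times with the mean step so edge slopes stay finite
    step <- if (nf > 1L) mean(diff(times)) else 0.01
    tpad <- c(times[1L] - (N:1) * step, times, times[nf] + (1:N) * step)
    for (t in seq_len(nf)) {
      idx <- t:(t + 2L * N)
      tau <- tpad[idx] - mean(tpad[idx])
      denom <- sum(tau^2)
      if (denom == 0) next
      D[t, ] <- 0.010 * (tau %*% pad[idx, , drop = FALSE]) / denom
    }
  }
  D
}

#' Export a feature matrix as CSV
#'
#' One row per frame with the standard `c0..c12, d0..d12, a0..a12` header,
#' for use with external classifiers.
#'
#' @param features Matrix from [mfcc_for_frames()].
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
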