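#' Frame set
#'
#' An ordered collection of sample-index frames over a signal of length `n`.
#' Frames are half-open `[start, end)` with 0-based indices. Contiguous
#' frame sets tile `[0, n)` exactly; overlapping sets (the fixed frame size
#' and rate scheme) have constant length and shift.
#'
#' @param start,end Integer vectors of 0-based frame edges, `start < end`.
#' @param source Character vector: one of `"primary"`, `"secondary"`,
#'   `"fixed"`, `"random"` per frame (recycled).
#' @param n Signal length in samples.
#' @param mode `"contiguous"` or `"overlapping"`.
#' @return A data frame of class `"frame_set"` with columns `start`, `end`,
#'   `source` and attributes `n` and `mode`.
#' @export
frame_set <- function(start, end, source = "primary", n, mode = "contiguous") {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == length(end), length(start) >= 1L,
            all(start >= 0L), all(start < end), all(end <= n))
  mode <- match.arg(mode, c("contiguous", "overlapping"))
  if (is.unsorted(start)) stop("frames must be sorted by start")
  if (mode == "contiguous") {
    if (start[1L] != 0L || end[length(end)] != n ||
        (length(start) > 1L && any(start[-1L] != end[-length(end)])))
      stop("contiguous frame set must tile [0, n) with no gaps or overlaps")
  }
  fs <- data.frame(start = start, end = end,
                   source = rep_len(as.character(source), length(start)))
  structure(fs, n = as.integer(n), mode = mode,
            class = c("frame_set", "data.frame"))
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d %s frames over %d samples\n",
              nrow(x), attr(x, "mode"), attr(x, "n")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more\n", nrow(x) - 10L))
  invisible(x)
}

frame_lengths <- function(frames) frames$end - frames$start

#' Build a contiguous frame set from boundary indices
#'
#' Boundaries are 0-based sample indices; 0 and `n` are added if absent.
#' Frames shorter than `min_len` samples are merged forward into their
#' successor (the merged frame is re-checked); a trailing sub-minimum frame
#' merges backward into its predecessor.
#'
#' @param boundaries Integer vector of boundary indices in `[0, n]`.
#' @param n Signal length in samples.
#' @param min_len Minimum frame length in samples (0 disables merging).
#' @param source Frame source label.
#' @return A contiguous [frame_set].
#' @examples
#' frames_from_boundaries(c(0, 50, 100), 100)
#' @export
frames_from_boundaries <- function(boundaries, n, min_len = 0L,
                                   source = "primary") {
  n <- as.integer(n)
  b <- sort(unique(c(0L, as.integer(boundaries), n)))
  if (any(b < 0L) || any(b > n)) stop("boundaries must lie in [0, n]")
  if (min_len > 0L && length(b) > 2L) {
    kept <- b[1L]
    for (k in 2L:(length(b) - 1L)) {
      if (b[k] - kept[length(kept)] >= min_len) kept <- c(kept, b[k])
    }
    kept <- c(kept, n)
    # trailing frame may still be short: merge backward
    m <- length(kept)
    if (m > 2L && kept[m] - kept[m - 1L] < min_len) kept <- kept[-(m - 1L)]
    b <- kept
  }
  frame_set(b[-length(b)], b[-1L], source = source, n = n)
}

#' Per-frame energy profile with relative thresholds
#'
#' Frame energy is the raw sum of squared samples (not length-normalized).
#' The mean energy `d` across frames sets two relative thresholds,
#' `theta_lower = alpha * d` and `theta_upper = beta * d`, used to pick the
#' intermediate-energy (consonant and transition) frames for secondary
#' re-segmentation.
#'
#' @param x A [waveform] or numeric vector.
#' @param frames A contiguous [frame_set].
#' @param fs Sampling rate (ignored if `x` is a waveform).
#' @param alpha,beta Threshold factors; defaults 0.32 and 0.8.
#' @return Object of class `"energy_profile"`: list with `E`, `d`,
#'   `theta_lower`, `theta_upper`, `alpha`, `beta`.
#' @examples
#' fr <- frames_from_boundaries(c(0, 2, 4), 4)
#' frame_energy(c(1, 1, 2, 2), fr, fs = 16000)
#' @export
frame_energy <- function(x, frames, fs = NULL, alpha = 0.32, beta = 0.8) {
  w <- .wave_parts(x, if (is.null(fs)) 1 else fs)
  if (!inherits(frames, "frame_set") || nrow(frames) == 0L)
    stop("frames must be a non-empty frame_set")
  if (attr(frames, "mode") != "contiguous")
    stop("frame energy requires a contiguous frame set")
  if (alpha >= beta) stop("alpha must be < beta")
  x2 <- c(0, cumsum(w$samples^2))
  E <- x2[frames$end + 1L] - x2[frames$start + 1L]
  d <- mean(E)
  structure(list(E = E, d = d, theta_lower = alpha * d,
                 theta_upper = beta * d, alpha = alpha, beta = beta),
            class = "energy_profile")
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf(
    "<energy_profile> %d frames, d = %.4g, thresholds [%.4g, %.4g] (alpha=%g, beta=%g)\n",
    length(x$E), x$d, x$theta_lower, x$theta_upper, x$alpha, x$beta))
  invisible(x)
}

#' Select frames for secondary re-segmentation
#'
#' A frame is selected when its energy lies inside the closed threshold
#' window `[theta_lower, theta_upper]`: intermediate energies mark consonant
#' and transition regions, while near-silent frames fall below and steady
#' vowel frames above the window.
#'
#' @param profile An [frame_energy()] result.
#' @return Logical vector, one element per frame.
#' @export
select_substitution_frames <- function(profile) {
  stopifnot(inherits(profile, "energy_profile"))
  profile$E >= profile$theta_lower & profile$E <= profile$theta_upper
}

#' Fixed frame size and rate segmentation (FFSR baseline)
#'
#' The conventional overlapping analysis grid: `frame_ms` windows advanced
#' by `shift_ms` (defaults 25 ms / 10 ms). Only frames fully inside the
#' signal are produced.
#'
#' @param n Signal length in samples.
#' @param fs Sampling rate in Hz.
#' @param frame_ms,shift_ms Frame length and shift in milliseconds.
#' @return An overlapping [frame_set] (contiguous when
#'   `frame_ms == shift_ms`).
#' @examples
#' ffsr_segment(16000, 16000)
#' @export
ffsr_segment <- function(n, fs, frame_ms = 25, shift_ms = 10) {
  n <- as.integer(n)
  flen <- as.integer(floor(fs * frame_ms / 1000 + 0.5))
  shift <- as.integer(floor(fs * shift_ms / 1000 + 0.5))
  if (n < flen) {
    warning("signal shorter than one frame; returning a single truncated frame")
    return(frame_set(0L, n, source = "fixed", n = n, mode = "overlapping"))
  }
  k <- (n - flen) %/% shift
  start <- (0:k) * shift
  mode <- if (flen == shift) "contiguous" else "overlapping"
  if (mode == "contiguous" && (k + 1L) * flen != n) {
    # non-dividing tiling: keep as overlapping bookkeeping (constant shift)
    mode <- "overlapping"
  }
  frame_set(start, start + flen, source = "fixed", n = n, mode = mode)
}

#' Random contiguous segmentation baseline
#'
#' Partitions `[0, n)` into `n_frames` frames whose interior boundaries are
#' drawn uniformly among positions that respect the minimum frame length;
#' reproducible from `seed`.
#'
#' @param n Signal length in samples.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param min_len Minimum frame length in samples.
#' @return A contiguous [frame_set] with `source = "random"`.
#' @export
random_segment <- function(n, n_frames, seed = NULL, min_len = 32L) {
  n <- as.integer(n); n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  slack <- n - n_frames * min_len
  if (slack < 0L) stop("infeasible n_frames for this signal length")
  if (n_frames == 1L)
    return(frame_set(0L, n, source = "random", n = n))
  draw <- function() {
    if (min_len < 1L) return(sort(sample.int(n - 1L, n_frames - 1L)))
    u <- sort(sample.int(slack + 1L, n_frames - 1L, replace = TRUE) - 1L)
    u + (1:(n_frames - 1L)) * min_len
  }
  interior <- if (is.null(seed)) draw() else with_seed(seed, draw())
  frame_set(c(0L, interior), c(interior, n), source = "random", n = n)
}

#' Reverse the order of frame lengths
#'
#' Produces the reversed-order control: the sequence of frame lengths (and
#' sources) of a contiguous frame set is reversed and re-laid-out from 0, so
#' the frame-length multiset and total coverage are preserved but the
#' alignment of frame sizes with the signal is destroyed.
#'
#' @param frames A contiguous [frame_set].
#' @param n Signal length (defaults to the frame set's).
#' @return A contiguous [frame_set].
#' @export
reverse_frame_order <- function(frames, n = attr(frames, "n")) {
  stopifnot(inherits(frames, "frame_set"),
            attr(frames, "mode") == "contiguous")
  len <- rev(frame_lengths(frames))
  b <- c(0L, cumsum(len))
  frame_set(b[-length(b)], b[-1L], source = rev(frames$source), n = n)
}

# Derive a child seed from a parent seed and stream indices, in double
# precision to avoid 32-bit overflow; result always in [0, 2^31 - 2].
derive_seed <- function(seed, ...) {
  acc <- as.numeric(seed) %% 2147483647
  for (k in c(...)) acc <- (acc * 48271 + as.numeric(k)) %% 2147483647
  as.integer(acc)
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write / read a segmentation label file
#'
#' Tab-separated, one row per frame: `start_sec`, `end_sec`, `source`, with
#' times in 6-decimal fixed-point seconds — readable by common audio
#' annotation tools. Reading converts back to sample indices by half-up
#' rounding, which round-trips exactly at 6 decimals for any rate up to
#' 192 kHz.
#'
#' @param frames A [frame_set].
#' @param fs Sampling rate in Hz.
#' @param path Output file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns a
#'   [frame_set].
#' @export
write_labels <- function(frames, fs, path) {
  stopifnot(inherits(frames, "frame_set"))
  df <- data.frame(start_sec = sprintf("%.6f", frames$start / fs),
                   end_sec = sprintf("%.6f", frames$end / fs),
                   source = frames$source)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @param n Signal length in samples (defaults to the last frame end).
#' @param mode Frame-set mode of the file being read.
#' @export
read_labels <- function(path, fs, n = NULL, mode = "contiguous") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("numeric", "numeric", "character"))
  start <- as.integer(floor(df$start_sec * fs + 0.5))
  end <- as.integer(floor(df$end_sec * fs + 0.5))
  if (is.null(n)) n <- max(end)
  frame_set(start, end, source = df$source, n = n, mode = mode)
}
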