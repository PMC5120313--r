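#' Specification of a synthetic consonant-vowel syllable
#'
#' Parameters of one stop-consonant + vowel token produced by the built-in
#' source-filter generator. Unspecified durations and f0 are drawn uniformly
#' from their admissible ranges (burst 5-15 ms, transition 30-60 ms, vowel
#' 100-250 ms, f0 80-220 Hz) using `seed`.
#'
#' @param consonant One of `"p"`, `"t"`, `"k"`, `"b"`, `"d"`, `"g"`.
#' @param vowel One of `"aa"`, `"ih"`, `"ah"`.
#' @param burst_dur,transition_dur,vowel_dur Durations in seconds, or `NULL`
#'   to draw from the range.
#' @param f0 Fundamental frequency in Hz, or `NULL` to draw.
#' @param burst_rms,transition_rms,vowel_rms Relative RMS levels of the three
#'   segments before peak normalization. Defaults (0.7, 0.9, 1.0) follow the
#'   level structure of natural stop syllables: the burst is an intense
#'   decaying transient (its instantaneous peak is the waveform maximum but
#'   its segment RMS stays below the vowel's), and the formant transition —
#'   the onset of voicing — sits within about 1 dB of the vowel.
#' @param seed Integer seed controlling all random draws for this token.
#' @param fs Sampling rate in Hz.
#' @return Object of class `"syllable_spec"`.
#' @examples
#' syllable_spec("b", "ih", seed = 4)
#' @export
syllable_spec <- function(consonant, vowel, burst_dur = NULL,
                          transition_dur = NULL, vowel_dur = NULL,
                          f0 = NULL, burst_rms = 0.7, transition_rms = 0.9,
                          vowel_rms = 1.0, seed = 1L, fs = 16000) {
  consonant <- match.arg(consonant, c("p", "t", "k", "b", "d", "g"))
  vowel <- match.arg(vowel, c("aa", "ih", "ah"))
  drawn <- with_seed(seed, list(
    burst = stats::runif(1, 0.005, 0.015),
    trans = stats::runif(1, 0.030, 0.060),
    vow = stats::runif(1, 0.100, 0.250),
    f0 = stats::runif(1, 80, 220)
  ))
  structure(list(
    consonant = consonant, vowel = vowel,
    burst_dur = if (is.null(burst_dur)) drawn$burst else burst_dur,
    transition_dur = if (is.null(transition_dur)) drawn$trans else transition_dur,
    vowel_dur = if (is.null(vowel_dur)) drawn$vow else vowel_dur,
    f0 = if (is.null(f0)) drawn$f0 else f0,
    burst_rms = burst_rms, transition_rms = transition_rms,
    vowel_rms = vowel_rms,
    seed = as.integer(seed), fs = fs
  ), class = "syllable_spec")
}

#' @export
print.syllable_spec <- function(x, ...) {
  cat(sprintf("<syllable_spec> /%s%s/ burst %.1f ms, transition %.1f ms, vowel %.1f ms, f0 %.0f Hz (seed %d)\n",
              x$consonant, substr(x$vowel, 1, 1), 1000 * x$burst_dur,
              1000 * x$transition_dur, 1000 * x$vowel_dur, x$f0, x$seed))
  invisible(x)
}

# Vowel formant targets (Hz) and bandwidths: canonical American English
# values for /aa/ ("bob"), /ih/ ("bit"), /ah/ ("but").
vowel_formants <- function(vowel) {
  F <- switch(vowel,
              aa = c(730, 1090, 2440),
              ih = c(390, 1990, 2550),
              ah = c(640, 1190, 2390))
  list(F = F, B = c(60, 90, 150))
}

# Burst spectral shaping per place of articulation and second-formant locus
# used as the transition onset: labial bursts are low-frequency dominated
# with a low F2 locus, alveolar bursts high-frequency with a high locus,
# velar bursts mid-frequency.
consonant_traits <- function(consonant) {
  place <- switch(consonant, p = , b = "labial", t = , d = "alveolar",
                  k = , g = "velar")
  list(
    place = place,
    voiced = consonant %in% c("b", "d", "g"),
    burst_band = switch(place, labial = c(300, 1200),
                        alveolar = c(3500, 7000), velar = c(1500, 2600)),
    f2_locus = switch(place, labial = 800, alveolar = 1800, velar = 2300)
  )
}

# Second-order resonator applied with piecewise-constant coefficients and
# carried filter state: y[t] = g x[t] + a1 y[t-1] + a2 y[t-2].
resonate <- function(x, fc, bw, fs) {
  # fc, bw may be vectors (one value per piece of equal-length pieces)
  stopifnot(length(fc) == length(bw))
  npiece <- length(fc)
  bounds <- floor(seq(0, length(x), length.out = npiece + 1L))
  y <- numeric(length(x))
  init <- c(0, 0)
  for (k in seq_len(npiece)) {
    i0 <- bounds[k] + 1L; i1 <- bounds[k + 1L]
    if (i1 < i0) next
    r <- exp(-pi * bw[k] / fs)
    a1 <- 2 * r * cos(2 * pi * fc[k] / fs)
    a2 <- -r^2
    g <- (1 - r) * sqrt(1 - 2 * r * cos(4 * pi * fc[k] / fs) + r^2) # ~unit peak gain
    seg <- stats::filter(g * x[i0:i1], c(a1, a2), method = "recursive",
                         init = init)
    y[i0:i1] <- seg
    init <- c(y[i1], if (i1 > i0) y[i1 - 1L] else init[1])
  }
  y
}

# Impulse-train glottal source. `f0` may be a length-2 vector (start, end)
# for linear declination; jitter and shimmer perturb each period/pulse.
glottal_pulses <- function(n, f0, fs, jitter = 0, shimmer = 0) {
  x <- numeric(n)
  f0 <- rep_len(f0, 2L)
  pos <- 1
  while (pos <= n) {
    amp <- 1 + shimmer * stats::rnorm(1)
    x[as.integer(floor(pos))] <- amp
    f_here <- f0[1] + (f0[2] - f0[1]) * pos / n
    period <- fs / f_here * (1 + jitter * stats::rnorm(1))
    pos <- pos + period
  }
  x
}

scale_rms <- function(x, target) {
  r <- sqrt(mean(x^2))
  if (r == 0) x else x * (target / r)
}

#' Synthesize a consonant-vowel syllable with ground truth
#'
#' Source-filter synthesis of a stop-consonant + vowel token: 20 ms leading
#' silence; a decaying noise-burst transient spectrally shaped by place of
#' articulation (voiced stops add low-frequency pre-voicing); a formant
#' transition whose three resonators glide linearly from the consonant loci
#' to the vowel targets — excited by aspiration noise over its first part
#' for voiceless stops (a long-VOT cue) and by glottal pulses for voiced
#' ones; a steady vowel (impulse train at `f0` through the three vowel
#' resonators) with a 20 ms onset rise from the transition level and a 30 ms
#' offset fade; and 20 ms trailing silence. A recording-noise floor at about
#' -50 dB re peak is added throughout. Relative segment levels follow
#' natural stop syllables (transition about -1 dB re vowel RMS; the burst a
#' loud but brief transient), so consonant-region frame energies register as
#' intermediate between silence and the vowel at the coarse frame scale —
#' the contrast the energy thresholding keys on. The waveform is
#' peak-normalized to 0.95.
#'
#' @param spec A [syllable_spec].
#' @return List with `wave` (a [waveform]), `truth` (list of 0-based
#'   half-open sample spans `burst_span`, `transition_span`, `vowel_span`)
#'   and `spec`.
#' @examples
#' syl <- synth_cv(syllable_spec("d", "ah", seed = 9))
#' syl$wave
#' @export
synth_cv <- function(spec) {
  stopifnot(inherits(spec, "syllable_spec"))
  fs <- spec$fs
  tr <- consonant_traits(spec$consonant)
  vf <- vowel_formants(spec$vowel)
  n_sil <- round(0.020 * fs)
  n_burst <- round(spec$burst_dur * fs)
  n_trans <- round(spec$transition_dur * fs)
  n_vow <- round(spec$vowel_dur * fs)

  with_seed(spec$seed + 211L, {
    # burst: place-shaped noise transient with a fast exponential decay
    burst <- bandpass_oscillation(stats::rnorm(n_burst), tr$burst_band, fs,
                                  order = 2)
    burst <- burst * exp(-(0:(n_burst - 1)) / (0.004 * fs))
    burst <- scale_rms(burst, spec$burst_rms)
    if (tr$voiced) {
      tb <- (0:(n_burst - 1)) / fs
      burst <- burst + 0.3 * spec$transition_rms * sin(2 * pi * 110 * tb)
    }

    # transition: gliding resonators; voiceless stops are aspiration-excited
    # over the first 60% (long VOT), voiced stops fully pulse-excited.
    # Aspiration drives only the upper resonators (F2, F3): the first formant
    # is voiced-excited only, so voicing onset adds low-frequency energy
    # abruptly, as in natural stops.
    src_v_t <- glottal_pulses(n_trans, spec$f0 * c(1.08, 1.02), fs,
                              jitter = 0.01, shimmer = 0.05)
    n_asp <- if (tr$voiced) 0L else round(0.6 * n_trans)
    src_hi <- src_v_t
    if (n_asp > 0) src_hi[1:n_asp] <- stats::rnorm(n_asp, sd = 0.25)
    src_lo <- src_v_t
    if (n_asp > 0) src_lo[1:n_asp] <- 0
    # rapid initial glide: formants reach the vowel targets within ~20 ms,
    # then hold — place cues are transient, as in natural stops
    npiece <- max(4L, n_trans %/% round(0.005 * fs))
    n_glide <- max(2L, round(npiece * min(1, 0.020 / spec$transition_dur)))
    onsets <- c(0.9 * vf$F[1], tr$f2_locus, 0.95 * vf$F[3])
    trans <- 0
    for (j in 1:3) {
      fc <- c(seq(onsets[j], vf$F[j], length.out = n_glide),
              rep(vf$F[j], npiece - n_glide))
      src_j <- if (j == 1L) src_lo else src_hi
      trans <- trans + resonate(src_j, fc, rep(vf$B[j] * 1.4, npiece), fs)
    }
    trans <- scale_rms(trans, spec$transition_rms)

    # quasi-steady vowel: f0 declination with jitter and shimmer, slight
    # formant drift toward neutral, onset rise, soft offset fade
    src_v <- glottal_pulses(n_vow, spec$f0 * c(1.02, 0.85), fs,
                            jitter = 0.01, shimmer = 0.05)
    vow <- 0
    npv <- max(4L, n_vow %/% round(0.010 * fs))
    neutral <- c(500, 1500, 2500)
    for (j in 1:3) {
      fc <- seq(vf$F[j], vf$F[j] + 0.06 * (neutral[j] - vf$F[j]),
                length.out = npv)
      vow <- vow + resonate(src_v, fc, rep(vf$B[j], npv), fs)
    }
    vow <- scale_rms(vow, spec$vowel_rms)
    n_rise <- min(n_vow, round(0.020 * fs))
    vow[1:n_rise] <- vow[1:n_rise] *
      seq(spec$transition_rms / spec$vowel_rms, 1, length.out = n_rise)
    n_off <- min(n_vow %/% 2L, round(0.030 * fs))
    if (n_off > 0)
      vow[(n_vow - n_off + 1):n_vow] <- vow[(n_vow - n_off + 1):n_vow] *
        seq(1, 0.05, length.out = n_off)

    x <- c(numeric(n_sil), burst, trans, vow, numeric(n_sil))
    x <- x / max(abs(x)) * 0.95
    # recording-noise floor at about -50 dB re peak: real captures never
    # contain digital zero, and degenerate all-identical silence frames
    # would make clean-trained emission models pathologically overconfident
    x <- x + stats::rnorm(length(x), sd = 0.003)
    x <- pmin(pmax(x, -1), 1)
    b0 <- as.integer(n_sil)
    truth <- list(
      burst_span = c(b0, b0 + as.integer(n_burst)),
      transition_span = b0 + as.integer(n_burst) + c(0L, as.integer(n_trans)),
      vowel_span = b0 + as.integer(n_burst) + as.integer(n_trans) +
        c(0L, as.integer(n_vow))
    )
    list(wave = waveform(x, fs), truth = truth, spec = spec)
  })
}

sd_or_one <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) 1 else s
}

#' Synthesize noise signals
#'
#' `"stationary"` is Gaussian noise with a fixed -6 dB/octave spectral tilt
#' above 500 Hz (a colored, temporally flat masker). `"babble_like"` sums 8
#' independently seeded streams of concatenated random CV syllables, giving
#' the slow (2-10 Hz) envelope modulation characteristic of competing talkers.
#' Output is RMS-normalized to 0.1.
#'
#' @param kind `"stationary"` or `"babble_like"`.
#' @param n_samples Length in samples.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @return A [waveform].
#' @examples
#' synth_noise("stationary", 8000, seed = 1)
#' @export
synth_noise <- function(kind = c("stationary", "babble_like"), n_samples,
                        seed = 1L, fs = 16000) {
  kind <- match.arg(kind)
  n_samples <- as.integer(n_samples)
  stopifnot(n_samples >= 1L)
  x <- with_seed(seed + 77L, {
    if (kind == "stationary") {
      z <- stats::rnorm(n_samples)
      f <- (0:(n_samples - 1)) / n_samples * fs
      f <- pmin(f, fs - f)
      shape <- 1 / (1 + f / 500) # -6 dB/oct above 500 Hz
      Re(stats::fft(stats::fft(z) * shape, inverse = TRUE)) / n_samples
    } else {
      acc <- numeric(n_samples)
      cons <- c("p", "t", "k", "b", "d", "g")
      vows <- c("aa", "ih", "ah")
      for (s in 1:8) {
        stream <- numeric(0)
        k <- 0L
        while (length(stream) < n_samples) {
          k <- k + 1L
          it_seed <- derive_seed(seed, s, k)
          pick <- with_seed(it_seed, c(sample.int(6L, 1L), sample.int(3L, 1L)))
          syl <- synth_cv(syllable_spec(cons[pick[1]], vows[pick[2]],
                                        seed = it_seed, fs = fs))
          stream <- c(stream, syl$wave$samples)
        }
        acc <- acc + stream[1:n_samples]
      }
      acc
    }
  })
  waveform(scale_rms(x, 0.1), fs)
}

#' Build a labeled synthetic CV corpus
#'
#' Generates `n_per_class` tokens per consonant class with per-item seeds
#' derived deterministically from the corpus seed; vowels and all durations
#' are drawn per item. Class labels are exactly balanced.
#'
#' @param n_per_class Tokens per class.
#' @param classes Consonant classes (default all six stops).
#' @param seed Corpus seed.
#' @param fs Sampling rate in Hz.
#' @return List of items, each a list with `wave`, `truth`, `label`, `spec`.
#' @examples
#' corp <- build_corpus(2, classes = c("p", "t"), seed = 1)
#' length(corp)
#' @export
build_corpus <- function(n_per_class, classes = c("p", "t", "k", "b", "d", "g"),
                         seed = 1L, fs = 16000) {
  stopifnot(n_per_class >= 1L)
  vows <- c("aa", "ih", "ah")
  out <- vector("list", n_per_class * length(classes))
  i <- 0L
  for (cls in classes) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      it_seed <- derive_seed(seed, i)
      vowel <- vows[(it_seed %% 3L) + 1L]
      syl <- synth_cv(syllable_spec(cls, vowel, seed = it_seed, fs = fs))
      out[[i]] <- list(wave = syl$wave, truth = syl$truth, label = cls,
                       spec = syl$spec)
    }
  }
  out
}

#' Syllable with envelope modulation concentrated at two rates
#'
#' A diagnostic stimulus for the band-combination scan: a noise carrier whose
#' amplitude envelope is modulated at a slow syllabic rate (`f_slow`, default
#' 7 Hz) everywhere and additionally at a fast rate (`f_fast`, default 30 Hz)
#' inside a weaker consonant-like region, while the carrier's spectral
#' content (a low vs high noise band) toggles exactly at the phase-quadrant
#' boundaries of the corresponding modulator. The CSE-maximizing nested
#' reference for such a stimulus is the band pair containing `f_slow` and
#' `f_fast`, because only those bands place frame boundaries at the spectral
#' switch points.
#'
#' @param seed Integer seed.
#' @param f_slow,f_fast Modulation rates in Hz.
#' @param dur Total duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return A [waveform].
#' @export
synth_band_probe <- function(seed = 1L, f_slow = 7, f_fast = 30, dur = 1.2,
                             fs = 16000) {
  n <- round(dur * fs)
  t <- (0:(n - 1)) / fs
  with_seed(seed + 389L, {
    # amplitude contour: slow modulation everywhere; a weaker, fast-modulated
    # consonant-like region in the middle 30% of the token
    c0 <- round(0.40 * n); c1 <- round(0.60 * n)
    inC <- seq_len(n) > c0 & seq_len(n) <= c1
    amp <- 1 + 0.2 * cos(2 * pi * f_slow * t)
    amp[inC] <- 0.55 * (1 + 0.6 * cos(2 * pi * f_fast * t[inC]))
    # spectral switch points: the phase-quadrant crossings of the contour's
    # own slow- and fast-band oscillations (the fast band governs inside the
    # consonant-like region), so boundaries derived from those bands bracket
    # spectrally pure stretches
    slow_band <- c(max(0.5, f_slow - 3), f_slow + 3)
    fast_band <- c(f_fast - 5, f_fast + 5)
    cr_s <- quadrant_crossings(instantaneous_phase(
      bandpass_oscillation(amp, slow_band, fs)))
    cr_f <- quadrant_crossings(instantaneous_phase(
      bandpass_oscillation(amp, fast_band, fs)))
    cuts <- sort(unique(c(0L, cr_s[cr_s <= c0 | cr_s > c1],
                          cr_f[cr_f > c0 & cr_f <= c1], n)))
    state <- integer(n)
    for (k in seq_len(length(cuts) - 1L)) {
      if (cuts[k + 1L] > cuts[k])
        state[(cuts[k] + 1L):cuts[k + 1L]] <- k %% 2L
    }
    lo <- scale_rms(bandpass_oscillation(stats::rnorm(n), c(200, 2500), fs,
                                         order = 2), 1)
    hi <- scale_rms(bandpass_oscillation(stats::rnorm(n), c(3000, 7000), fs,
                                         order = 2), 1)
    x <- amp * ifelse(state == 0L, lo, hi)
    waveform(x / max(abs(x)) * 0.95, fs)
  })
}
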