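#' Noise-robustness recognition benchmark on the synthetic corpus
#'
#' End-to-end comparison of segmentation schemes: builds disjoint train and
#' test CV corpora, extracts MFCC features over each scheme's frames, trains
#' clean-speech HMMs per class, and evaluates accuracy on clean test speech
#' and on noisy mixtures for every (noise kind, SNR) cell. Noise is added to
#' the test data only; models are always trained on clean speech.
#'
#' @param n_train,n_test Tokens per class in the train and test corpora.
#' @param classes Consonant classes.
#' @param schemes Character vector among `"NVFS"`, `"FFSR"`.
#' @param noise_kinds Noise kinds for [synth_noise()].
#' @param snrs_db SNR levels in dB for the noisy test conditions.
#' @param seed Integer seed driving corpus generation and noise draws.
#' @param n_states,n_mix HMM topology.
#' @param fs Sampling rate in Hz.
#' @param verbose Emit progress to stderr.
#' @return Data frame with columns `noise_type` (`"clean"` for the clean
#'   condition), `snr_db` (`NA` for clean), `scheme`, `accuracy` (percent).
#' @export
noise_benchmark <- function(n_train = 60L, n_test = 24L,
                            classes = c("p", "t", "k", "b", "d", "g"),
                            schemes = c("NVFS", "FFSR"),
                            noise_kinds = c("stationary", "babble_like"),
                            snrs_db = c(20, 10, 0), seed = 1L,
                            n_states = 4L, n_mix = 5L, fs = 16000,
                            verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  train <- build_corpus(n_train, classes, seed = seed, fs = fs)
  test <- build_corpus(n_test, classes, seed = seed + 5000L, fs = fs)
  lab_tr <- vapply(train, `[[`, "", "label")
  lab_te <- vapply(test, `[[`, "", "label")

  # Segmentation runs on the full token (the onset pad anchors the primary
  # oscillation's phase), but frames lying entirely inside the 20 ms
  # silence pads are excluded from the feature sequence — the frame-level
  # equivalent of the endpointing any isolated-unit recognizer performs.
  pad <- round(0.020 * fs)
  featurize <- function(wave, scheme) {
    n <- length(wave$samples)
    fr <- if (scheme == "NVFS") nvfs(wave)$frames
          else ffsr_segment(n, wave$fs)
    f <- mfcc_for_frames(wave, fr)
    f[!(fr$end <= pad | fr$start >= n - pad), , drop = FALSE]
  }

  # noisy test waveforms, shared across schemes so the comparison is paired
  conditions <- data.frame(noise_type = "clean", snr_db = NA_real_)
  for (nk in noise_kinds) for (s in snrs_db)
    conditions <- rbind(conditions,
                        data.frame(noise_type = nk, snr_db = s))
  test_waves <- vector("list", nrow(conditions))
  test_waves[[1L]] <- lapply(test, `[[`, "wave")
  for (ci in seq_len(nrow(conditions))[-1L]) {
    nk <- conditions$noise_type[ci]; s <- conditions$snr_db[ci]
    test_waves[[ci]] <- lapply(seq_along(test), function(i) {
      nz_seed <- derive_seed(seed, ci, i)
      nz <- synth_noise(nk, length(test[[i]]$wave$samples) + fs %/% 2L,
                        seed = nz_seed, fs = fs)
      mix_at_snr(test[[i]]$wave, nz, s, seed = nz_seed)
    })
  }

  out <- NULL
  for (scheme in schemes) {
    say("[%s] extracting training features (%d utterances)", scheme, length(train))
    f_tr <- lapply(train, function(it) featurize(it$wave, scheme))
    say("[%s] training %d-class HMMs", scheme, length(classes))
    mod <- train_models(f_tr, lab_tr, n_states = n_states, n_mix = n_mix)
    for (ci in seq_len(nrow(conditions))) {
      f_te <- lapply(test_waves[[ci]], featurize, scheme = scheme)
      acc <- evaluate_models(mod, f_te, lab_te)
      say("[%s] %s / %s dB: %.1f%%", scheme, conditions$noise_type[ci],
          format(conditions$snr_db[ci]), acc)
      out <- rbind(out, data.frame(noise_type = conditions$noise_type[ci],
                                   snr_db = conditions$snr_db[ci],
                                   scheme = scheme, accuracy = acc))
    }
  }
  rownames(out) <- NULL
  out
}

#' Mean CSE of competing segmentation schemes over a corpus
#'
#' For each corpus item computes the CSE of the nested (NVFS) segmentation,
#' the fixed 25/10 ms grid, the reversed-order control and (optionally) the
#' mean over seeded random segmentations with the same frame count as the
#' NVFS result.
#'
#' @param corpus List of items from [build_corpus()].
#' @param random_reps Random segmentations per item (0 disables).
#' @param seed Seed for the random-segmentation draws.
#' @return Data frame, one row per item, columns `nvfs`, `ffsr`, `reversed`
#'   and (if enabled) `random`.
#' @export
cse_comparison <- function(corpus, random_reps = 0L, seed = 1L) {
  rows <- lapply(seq_along(corpus), function(i) {
    wv <- corpus[[i]]$wave
    n <- length(wv$samples)
    fit <- nvfs(wv)
    v_nvfs <- cse(wv, fit$frames)$value
    v_ffsr <- cse(wv, ffsr_segment(n, wv$fs))$value
    v_rev <- cse(wv, reverse_frame_order(fit$frames))$value
    row <- data.frame(nvfs = v_nvfs, ffsr = v_ffsr, reversed = v_rev)
    if (random_reps > 0L) {
      k <- max(2L, nrow(fit$frames))
      vals <- vapply(seq_len(random_reps), function(r) {
        fr <- random_segment(n, k, seed = derive_seed(seed, i, r))
        cse(wv, fr)$value
      }, numeric(1))
      row$random <- mean(vals)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Boundary displacement between clean and noisy segmentations
#'
#' Segments the clean and noise-corrupted versions of a waveform and
#' reports, for each clean boundary, the absolute distance (ms) to the
#' nearest noisy boundary.
#'
#' @param wave Clean [waveform].
#' @param noisy Noisy [waveform] (same length).
#' @param ... Passed to [nvfs()].
#' @return Numeric vector of per-boundary displacements in milliseconds.
#' @export
boundary_displacement_ms <- function(wave, noisy, ...) {
  b1 <- boundaries(nvfs(wave, ...))
  b2 <- boundaries(nvfs(noisy, ...))
  vapply(b1, function(b) min(abs(b2 - b)), numeric(1)) * 1000 / wave$fs
}
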