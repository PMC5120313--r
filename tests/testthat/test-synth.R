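fs <- 16000

test_that("syllable synthesis is deterministic with exact ground-truth spans", {
  s1 <- synth_cv(syllable_spec("t", "aa", seed = 12))
  s2 <- synth_cv(syllable_spec("t", "aa", seed = 12))
  expect_identical(s1$wave$samples, s2$wave$samples)

  tr <- s1$truth
  expect_identical(tr$burst_span[1], 320L)
  expect_identical(tr$burst_span[2], tr$transition_span[1])
  expect_identical(tr$transition_span[2], tr$vowel_span[1])
  n <- length(s1$wave$samples)
  expect_identical(tr$vowel_span[2] + 320L, n)

  # drawn durations respect the admissible ranges
  spec <- s1$spec
  expect_true(spec$burst_dur >= 0.005 && spec$burst_dur <= 0.015)
  expect_true(spec$transition_dur >= 0.030 && spec$transition_dur <= 0.060)
  expect_true(spec$vowel_dur >= 0.100 && spec$vowel_dur <= 0.250)
  expect_true(spec$f0 >= 80 && spec$f0 <= 220)

  expect_true(all(is.finite(s1$wave$samples)))
  expect_lte(max(abs(s1$wave$samples)), 1)
  expect_error(syllable_spec("x", "aa"), "should be one of")
})

test_that("vowel is louder than the burst and quasi-periodic at f0", {
  for (s in c(12, 31)) {
    syl <- synth_cv(syllable_spec("p", "aa", seed = s, f0 = 120))
    x <- syl$wave$samples
    tr <- syl$truth
    rms <- function(sp) sqrt(mean(x[(sp[1] + 1):sp[2]]^2))
    expect_gt(rms(syl$truth$vowel_span), rms(syl$truth$burst_span))

    # envelope autocorrelation inside the vowel peaks near one pitch period
    vs <- tr$vowel_span
    env <- hilbert_envelope(x[(vs[1] + 1):vs[2]], fs)
    env <- env - mean(env)
    ac <- acf(env, lag.max = round(fs / 80), plot = FALSE)$acf[-1]
    lo <- round(fs / (120 * 1.25)); hi <- round(fs / (120 * 0.8))
    peak <- lo - 1 + which.max(ac[lo:hi])
    f_est <- fs / peak
    expect_lt(abs(f_est - 120) / 120, 0.25) # declination widens the band
  }
})

test_that("noise generators are seeded and have the intended temporal texture", {
  n1 <- synth_noise("stationary", 16000, seed = 4)
  expect_identical(n1$samples, synth_noise("stationary", 16000, seed = 4)$samples)

  # stationarity: long-window band spectra of the two halves agree within 3 dB
  spec_db <- function(x) {
    p <- Mod(fft(x * (0.54 - 0.46 * cos(2 * pi * seq_along(x) / length(x)))))^2
    bands <- split(p[2:4000], cut(2:4000, 8))
    10 * log10(vapply(bands, mean, numeric(1)))
  }
  h1 <- spec_db(n1$samples[1:8000]); h2 <- spec_db(n1$samples[8001:16000])
  expect_lt(max(abs(h1 - h2)), 3)

  # babble carries more 2-10 Hz envelope modulation than stationary noise
  bb <- synth_noise("babble_like", 16000, seed = 4)
  modpow <- function(w) {
    e <- hilbert_envelope(w$samples, fs)
    mean(bandpass_oscillation(e / mean(e), c(2, 10), fs)^2)
  }
  expect_gt(modpow(bb), modpow(n1))
})

test_that("corpus construction is balanced, labeled and split-disjoint", {
  corp <- build_corpus(10, seed = 1)
  expect_length(corp, 60L)
  expect_identical(as.vector(table(vapply(corp, `[[`, "", "label"))),
                   rep(10L, 6L))

  corp2 <- build_corpus(3, classes = c("p", "t"), seed = 2)
  expect_length(corp2, 6L)

  train <- build_corpus(2, seed = 1)
  test <- build_corpus(2, seed = 5001)
  for (i in seq_along(train)) {
    expect_false(identical(train[[i]]$wave$samples, test[[i]]$wave$samples))
  }
})
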