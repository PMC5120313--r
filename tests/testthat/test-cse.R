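fs <- 16000

test_that("ERB filterbank energies are unit-norm and frequency-selective", {
  set.seed(3)
  wn <- erb_filterbank_energies(rnorm(400), fs)
  expect_length(wn, 33L)
  expect_true(all(wn > 0))
  expect_equal(sqrt(sum(wn^2)), 1, tolerance = 1e-9)

  tn <- erb_filterbank_energies(tone(1000, dur = 0.025), fs)
  cf <- attr(tn, "center_freqs")
  expect_lt(abs(cf[which.max(tn)] - 1000), 200)
  expect_equal(sqrt(sum(tn^2)), 1, tolerance = 1e-9)

  expect_identical(sum(erb_filterbank_energies(numeric(400), fs)), 0)
  expect_error(erb_filterbank_energies(numeric(10), fs), "shorter than minimum")
})

test_that("CSE is zero for identical frames and sqrt(2) for disjoint spectra", {
  # identical copies of the same segment in every frame
  set.seed(4)
  seg <- rnorm(512)
  x <- rep(seg, 4)
  fr <- frames_from_boundaries(c(0, 512, 1024, 1536), length(x))
  r <- cse(x, fr, fs)
  expect_equal(r$value, 0, tolerance = 1e-12)
  expect_identical(r$n_frames, 4L)

  # two frames with energy in disjoint channel sets
  x2 <- c(tone(300, dur = 0.032), tone(5000, dur = 0.032))
  fr2 <- frames_from_boundaries(c(0, 512), length(x2))
  r2 <- cse(x2, fr2, fs)
  expect_equal(r2$value, sqrt(2), tolerance = 0.05)
  expect_length(r2$distances, 1L)

  expect_error(cse(x2, frames_from_boundaries(integer(0), length(x2)), fs),
               "fewer than 2")
})

test_that("CSE is scale invariant with distances bounded in [0, 2]", {
  syl <- fixture_syllable(seed = 7)
  fit <- nvfs(syl$wave)
  r1 <- cse(syl$wave, fit$frames)
  r2 <- cse(waveform(2.9 * syl$wave$samples, fs), fit$frames)
  expect_equal(r1$value, r2$value, tolerance = 1e-9)
  expect_true(all(r1$distances >= 0 & r1$distances <= 2))
  expect_gte(r1$value, 0)
  expect_lte(r1$value, 2)
  expect_equal(r1$value, mean(r1$distances))
})

test_that("random-segmentation CSE is seed-reproducible and concentrates with reps", {
  syl <- fixture_syllable(seed = 7)
  wv <- syl$wave
  n <- length(wv$samples)
  mean_over <- function(reps, base) {
    mean(vapply(seq_len(reps), function(r)
      cse(wv, random_segment(n, 9, seed = base + r))$value, numeric(1)))
  }
  expect_identical(mean_over(40, 100), mean_over(40, 100))

  # Monte-Carlo spread shrinks roughly as 1/sqrt(reps)
  m100 <- vapply(1:6, function(k) mean_over(25, 1000 * k), numeric(1))
  m400 <- vapply(1:6, function(k) mean_over(100, 50000 + 1000 * k), numeric(1))
  expect_lt(sd(m400), sd(m100))
})

test_that("band scan enumerates all ordered pairs and ranks by CSE", {
  syl <- fixture_syllable(seed = 9, consonant = "k", vowel = "ih")
  bs <- band_scan(syl$wave)
  expect_identical(nrow(bs), 30L)
  expect_identical(anyDuplicated(bs[c("primary", "secondary")]), 0L)
  expect_true(all(bs$primary != bs$secondary))
  ok <- !is.na(bs$cse)
  expect_true(!is.unsorted(rev(bs$cse[ok])))
  expect_equal(as.numeric(bs$rank), as.numeric(1:30))
})

test_that("the scan recovers the band pair carrying the envelope modulation", {
  pr <- synth_band_probe(seed = 3)
  bs <- band_scan(pr)
  expect_identical(bs$primary[1], "theta")
  expect_identical(bs$secondary[1], "low_gamma")
})
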