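fs <- 16000

test_that("analytic signal has exact real part and the Hilbert pair of a cosine", {
  x <- tone(1000)
  a <- analytic_signal(x, fs)
  expect_identical(Re(a), x)

  # imaginary part of the analytic cosine is the matching sine
  s <- sin(2 * pi * 1000 * (0:(fs - 1)) / fs)
  interior <- (0.01 * fs):(0.99 * fs)
  expect_lt(max(abs(Im(a)[interior] - s[interior])), 1e-3)

  expect_identical(analytic_signal(numeric(100) , fs), complex(real = numeric(100), imaginary = numeric(100)))
  expect_error(analytic_signal(numeric(0), fs), "empty signal")

  set.seed(42)
  r <- rnorm(512)
  expect_identical(Re(analytic_signal(r, fs)), r)
})

test_that("Hilbert envelope recovers tone amplitude and AM modulator", {
  interior <- (0.05 * fs):(0.95 * fs)

  env <- hilbert_envelope(tone(2000, amp = 0.5), fs)
  expect_true(all(env >= 0))
  expect_lt(sqrt(mean((env[interior] - 0.5)^2)) / 0.5, 0.02)

  t <- (0:(fs - 1)) / fs
  mod <- 1 + 0.5 * cos(2 * pi * 5 * t)
  env2 <- hilbert_envelope(mod * cos(2 * pi * 2000 * t), fs)
  rel <- sqrt(sum((env2[interior] - mod[interior])^2) / sum(mod[interior]^2))
  expect_lt(rel, 0.02)

  expect_identical(hilbert_envelope(numeric(64), fs), numeric(64))
})

test_that("envelope bounds the signal and scales linearly", {
  set.seed(3)
  x <- rnorm(2048)
  env <- hilbert_envelope(x, fs)
  expect_true(all(env >= abs(x) - 1e-9))
  expect_equal(hilbert_envelope(2.5 * x, fs), 2.5 * env, tolerance = 1e-9)
})

test_that("bandpass oscillation matches a third-order Butterworth response", {
  n <- 2 * fs
  interior <- (fs %/% 2):(3 * fs %/% 2)

  # DC fully rejected by the theta bandpass
  dc <- bandpass_oscillation(rep(1, fs), "theta", fs)
  expect_lt(max(abs(dc[(0.2 * fs):(0.8 * fs)])), 1e-3)

  # in-band tone preserved, out-of-band tone strongly attenuated
  g7 <- sqrt(2 * mean(bandpass_oscillation(tone(7, 2), "theta", fs)[interior]^2))
  g30 <- sqrt(2 * mean(bandpass_oscillation(tone(30, 2), "theta", fs)[interior]^2))
  expect_gt(g7, 0.9)
  expect_lt(g7, 1.1)
  expect_gt(20 * log10(g7 / g30), 18)

  # mix separates
  mix <- tone(7, 2) + tone(30, 2)
  y <- bandpass_oscillation(mix, "theta", fs)
  expect_lt(sqrt(mean((y[interior] - tone(7, 2)[interior])^2)), 0.1)

  expect_error(bandpass_oscillation(rnorm(100), c(7000, 9000), fs),
               "band above Nyquist")
})

test_that("instantaneous phase of a tone is linear and wrapped to (-pi, pi]", {
  osc <- tone(7)
  phi <- instantaneous_phase(osc)
  expect_true(all(phi > -pi & phi <= pi))
  expect_lt(abs(phi[1]), 0.05) # cosine starts at phase ~0

  up <- cumsum(c(phi[1], ((diff(phi) + pi) %% (2 * pi)) - pi)) # unwrap
  interior <- (0.1 * fs):(0.9 * fs)
  slope <- coef(lm(up[interior] ~ interior))[2]
  expect_equal(as.numeric(slope), 2 * pi * 7 / fs, tolerance = 0.01)

  expect_error(instantaneous_phase(numeric(128)), "degenerate oscillation")

  set.seed(5)
  phi_r <- instantaneous_phase(rnorm(256))
  expect_true(all(phi_r > -pi & phi_r <= pi))
})

test_that("quadrant labels follow the half-open convention with endpoint rule", {
  expect_identical(quadrant_labels(c(-pi, -pi / 2 - 0.01, -pi / 2, -0.01, 0,
                                     0.1, pi / 2 - 0.01, pi / 2, pi)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 4L, 4L))

  # one full cycle: each quadrant holds ~1/4 of samples
  phi <- instantaneous_phase(tone(4, dur = 1))
  counts <- tabulate(quadrant_labels(phi), 4)
  expect_true(all(abs(counts / length(phi) - 0.25) < 0.02))
})

test_that("quadrant crossings count 4 per cycle with quarter-period spacing", {
  phi <- instantaneous_phase(tone(7))
  b <- quadrant_crossings(phi)
  expect_identical(b[1], 0L)
  expect_identical(b[length(b)], length(phi))
  expect_true(all(diff(b) > 0))

  n_interior <- length(b) - 2L
  expect_true(abs(n_interior - 28L) <= 1L)
  spacing <- diff(b[-c(1, length(b))])
  expect_true(all(abs(spacing - fs / 28) <= 2))

  # constant-quadrant phase: outer boundaries only
  expect_identical(quadrant_crossings(rep(0.3, 500)), c(0L, 500L))
})
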