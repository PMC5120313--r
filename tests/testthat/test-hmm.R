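fs <- 16000

test_that("noise mixing hits the requested SNR exactly", {
  syl <- fixture_syllable(seed = 7)
  nz <- synth_noise("stationary", length(syl$wave$samples) + 4000, seed = 2)
  for (snr in c(0, 20, 7.5)) {
    mixed <- mix_at_snr(syl$wave, nz, snr, seed = 5)
    ncomp <- attr(mixed, "noise")
    ps <- mean(syl$wave$samples^2)
    pn <- mean(ncomp^2)
    expect_equal(10 * log10(ps / pn), snr, tolerance = 0.01)
    expect_equal(mixed$samples, syl$wave$samples + ncomp, tolerance = 1e-12)
  }
  expect_error(mix_at_snr(numeric(100) + 0, nz, 10, fs = fs), "zero-power")
})

# two well-separated synthetic classes: sequences of Gaussian frames whose
# means differ by far more than the within-class spread
sep_classes <- function(n_seq, seed, d = 6L, gap = 8) {
  set.seed(seed)
  make <- function(mu) {
    lapply(seq_len(n_seq), function(i) {
      TT <- sample(8:14, 1)
      matrix(rnorm(TT * d, mean = mu), TT, d)
    })
  }
  list(a = make(0), b = make(gap))
}

test_that("EM training log-likelihood is non-decreasing", {
  cls <- sep_classes(8, seed = 5)
  feats <- c(cls$a, cls$b)
  labs <- rep(c("a", "b"), each = 8)
  seqs <- cls$a
  for (M in c(1L, 2L)) {
    m0 <- nvfs:::init_hmm(seqs, 3L, 6L)
    if (M > 1L) m0 <- nvfs:::split_mixtures(m0, M)
    m1 <- nvfs:::train_hmm_em(seqs, m0, max_iter = 25L)
    expect_gt(length(m1$loglik_trace), 1L)
    expect_true(all(diff(m1$loglik_trace) >= -1e-8))
  }
})

test_that("linearly separable classes are classified perfectly and deterministically", {
  cls <- sep_classes(10, seed = 5)
  feats <- c(cls$a, cls$b)
  labs <- rep(c("a", "b"), each = 10)
  mod <- train_models(feats, labs, n_states = 2L, n_mix = 2L)

  held <- sep_classes(6, seed = 99)
  test_feats <- c(held$a, held$b)
  test_labs <- rep(c("a", "b"), each = 6)
  expect_equal(evaluate_models(mod, test_feats, test_labs), 100)

  p1 <- predict(mod, test_feats)
  mod2 <- train_models(feats, labs, n_states = 2L, n_mix = 2L)
  p2 <- predict(mod2, test_feats)
  expect_identical(as.character(p1), as.character(p2))
  L <- attr(p1, "loglik")
  expect_identical(dim(L), c(12L, 2L))

  # training-set evaluation is perfect too
  expect_equal(evaluate_models(mod, feats, labs), 100)
})

test_that("accuracy is invariant to test-set order and matches chance for noise", {
  cls <- sep_classes(10, seed = 5)
  feats <- c(cls$a, cls$b)
  labs <- rep(c("a", "b"), each = 10)
  mod <- train_models(feats, labs, n_states = 2L, n_mix = 2L)

  held <- sep_classes(6, seed = 99)
  test_feats <- c(held$a, held$b)
  test_labs <- rep(c("a", "b"), each = 6)
  perm <- c(7, 2, 11, 4, 1, 12, 3, 9, 5, 10, 8, 6)
  expect_equal(evaluate_models(mod, test_feats[perm], test_labs[perm]),
               evaluate_models(mod, test_feats, test_labs))

  # far-from-training random sequences: decisions split roughly at chance
  set.seed(123)
  rand <- lapply(1:40, function(i) matrix(rnorm(10 * 6, mean = 4), 10, 6))
  pr <- predict(mod, rand)
  expect_gt(mean(pr == "a"), 0.2)
  expect_lt(mean(pr == "a"), 0.8)
})

test_that("training input is validated", {
  cls <- sep_classes(3, seed = 1)
  expect_error(train_models(cls$a, rep("a", 3)), "at least 2 classes")
  expect_error(train_models(c(cls$a, cls$b), rep(c("a", "b"), each = 3)),
               "at least 5 sequences")
})
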