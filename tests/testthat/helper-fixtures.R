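# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

fixture_syllable <- function(seed = 7, consonant = "p", vowel = "aa", ...) {
  fixture(paste("syl", seed, consonant, vowel), function()
    synth_cv(syllable_spec(consonant, vowel, seed = seed, ...)))
}

fixture_corpus <- function(n_per_class, seed, classes = c("p", "t", "k", "b", "d", "g")) {
  fixture(paste("corp", n_per_class, seed, paste(classes, collapse = "")),
          function() build_corpus(n_per_class, classes, seed = seed))
}

# pure tone helper
tone <- function(f, dur = 1, fs = 16000, amp = 1, phase = 0) {
  amp * cos(2 * pi * f * (0:(round(dur * fs) - 1)) / fs + phase)
}

# mean frame duration (ms) of frames whose midpoint falls in a span
mean_dur_in_span <- function(frames, span, fs = 16000) {
  mid <- (frames$start + frames$end) / 2
  len <- (frames$end - frames$start) / fs * 1000
  mean(len[mid >= span[1] & mid < span[2]])
}
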