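---
title: "Oscillation-guided speech segmentation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillation-guided speech segmentation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(nvfs)
```

## The model

Conventional speech front ends segment the signal on an external clock: a
25 ms analysis window advanced every 10 ms (the fixed frame size and rate
scheme, FFSR). That grid ignores the quasi-regular temporal structure of
speech — a stop-consonant burst lives on a 5–15 ms scale, a steady vowel on a
100–250 ms scale — so a fixed window simultaneously smears transients and
oversamples steady spans.

This package implements the alternative this family of methods proposes: let
the signal's own slow amplitude dynamics supply the clock. The pipeline is:

1. **Envelope.** The amplitude envelope $a(n) = |s_r(n) + i\,\hat s_r(n)|$
   is the magnitude of the analytic signal, with $\hat s_r$ the Hilbert
   transform of the waveform $s_r$.
2. **Primary oscillation.** A third-order Butterworth bandpass applied to
   $a(n)$ with zero net group delay extracts the *primary* modulation band,
   by default theta (4–10 Hz), the band that tracks syllable-scale events.
3. **Phase partition.** The instantaneous phase $\phi(n)$ of the primary
   oscillation (angle of its analytic signal) is split into four quadrants
   $[-\pi,-\pi/2)$, $[-\pi/2,0)$, $[0,\pi/2)$, $[\pi/2,\pi]$; every quadrant
   crossing is a frame boundary. A pure in-band oscillation at $f$ Hz
   therefore yields $4f$ boundaries per second at quarter-period spacing.
4. **Energy gate.** Each primary frame's energy is the raw sum of squares
   $E_i = \sum_{n \in \text{frame } i} s_r(n)^2$, and
   $d = \tfrac{1}{N}\sum_i E_i$ is their mean. Frames with
   $\alpha d \le E_i \le \beta d$ (defaults $\alpha = 0.32$,
   $\beta = 0.8$) are flagged as consonant/transition material: silence
   falls below the window, steady vowels above it.
5. **Secondary substitution.** Inside every flagged frame the same phase
   partition is applied to the *secondary* band oscillation (default low
   gamma, 25–35 Hz), replacing the single coarse frame with quarter-period
   sub-frames of roughly 7–10 ms. The two-band composite is the *nested
   oscillatory reference*; exactly one level of nesting is performed.

The result is a contiguous tiling of the utterance in which short frames
concentrate on bursts and formant transitions and long frames cover vowels.
`nvfs()` returns the frame set together with the nested reference signal,
per-sample band and quadrant tags, and the energy profile; `print()`,
`summary()` and `plot()` methods display them.

Two quantities evaluate a segmentation:

* **Cochlea-scaled spectral entropy (CSE).** Each frame is reduced to a
  33-channel spectrum on the ERB (equivalent rectangular bandwidth) scale,
  normalized to unit Euclidean length; the CSE is the mean Euclidean
  distance between adjacent frames' spectra. Boundaries placed at genuine
  spectral change points raise it; boundaries wasted inside steady spans
  dilute it. Distances are bounded by $[0, 2]$ and the measure is invariant
  to signal gain.
* **Recognition accuracy.** 13 mel-frequency cepstral coefficients plus
  first and second derivatives (39 dimensions) are computed per frame and
  classified by per-class left-to-right hidden Markov models with 4 states
  and 5 diagonal-covariance Gaussian mixtures per state, trained on clean
  speech and tested under additive noise at controlled SNR.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `primary_band` | theta, 4–10 | Hz | syllable-scale frame clock |
| `secondary_band` | low gamma, 25–35 | Hz | sub-phonemic re-segmentation clock |
| `alpha`, `beta` | 0.32, 0.8 | — | relative energy window selecting frames to re-segment |
| `min_frame_ms` | 2 | ms | minimum frame; shorter frames merge into their successor |
| FFSR frame/shift | 25 / 10 | ms | conventional baseline grid |
| ERB channels | 33 over 100–7500 | — / Hz | spectral resolution of the CSE |
| MFCC | 13 cepstra, 26 mel filters | — | recognition front end |
| HMM | 4 states, 5 mixtures | — | per-class acoustic model |

The band pair and the two threshold factors are the published operating
point of the method; the package exposes them as arguments (and through
`nvfs_config()`) but does not refit them — refitting $\alpha,\beta$ would
require a manually aligned phone-boundary corpus. `band_scan()` reproduces
the selection *procedure* for the band pair: it runs the nested segmentation
for all 30 ordered pairs of the six canonical bands (delta 0.4–4, theta
4–10, alpha 11–16, beta 16–25, low gamma 25–35, mid gamma 35–50 Hz) and
ranks them by CSE.

## Numerical choices

**Zero-phase band filtering.** Frame boundaries are phase-derived, so the
band filters must add no group delay; forward–backward filtering is the
standard answer. A direct recursive implementation is unusable here: at a
16 kHz rate the delta and theta bands have normalized widths of order
$10^{-4}$, where the bilinear-transform pole positions of even a 3rd-order
Butterworth round into instability (measured output magnitudes of order
$10^{32}$). The filters are therefore applied in the frequency domain as
the exact bilinear-prewarped Butterworth magnitude-squared response
$|H(\omega)|^2 = 1/(1 + r(\omega)^{6})$ with
$r = (\Omega^2 - \Omega_l\Omega_u) / ((\Omega_u - \Omega_l)\,\Omega)$ and
$\Omega = \tan(\omega/2)$ — the steady-state equivalent of
forward–backward filtering — after mirror extension of the signal to
suppress wrap-around. Passband gain and stopband rolloff were verified
against `signal::filtfilt` in a band where the latter is stable, and
against the analytic response.

**Quadrant conventions.** The four printed phase quadrants share endpoints;
the package fixes half-open intervals with ties assigned upward and the two
outer endpoints mapped to their printed quadrants ($-\pi \to 1$,
$\pi \to 4$). Boundary indices are 0-based and frames half-open, so every
segmentation tiles $[0, N)$ exactly.

**Frame energy.** $E_i$ is the raw (not length-normalized) sum of squares,
because the published $\alpha, \beta$ were fitted under that formula. The
printed form of the thresholding inequality is garbled in the source text;
the implemented reading — substitute when
$\theta_{lower} \le E_i \le \theta_{upper}$, inclusive — follows the
surrounding prose ("distinguishes the consonant and transition regions from
the salient and vowel regions") and is covered by tests. Both thresholds
scale with $d$, which makes the segmentation exactly gain-invariant.

**Short frames.** Sub-minimum frames (default 2 ms = 32 samples) are merged
greedily into their successor, the last frame backward, so every frame can
support spectral analysis. Secondary extraction band-passes the globally
computed envelope rather than an isolated snippet: a 25–35 Hz filter on a
30 ms excerpt would be all edge transient.

**Variance flooring.** Mixture variances are floored at 1% of the global
per-dimension training variance (absolute lower bound $10^{-4}$). This is
the HTK convention (`HCompV` vFloors); a purely absolute floor lets a
mixture that captures near-identical frames collapse to absurd confidence,
which turns any train/test mismatch into numerically dominant penalties.

**Recognition harness.** Models are trained on clean tokens only and tested
on noisy mixtures, with the noise scaled so that
$10\log_{10}(P_s/P_n)$ over the full utterance equals the requested SNR.
Tokens are segmented with their 20 ms silence pads attached (the onset pad
anchors the primary oscillation's phase), but frames lying entirely inside
the pads are dropped from the feature sequences of both schemes — the
frame-level form of the endpointing any isolated-unit recognizer performs,
and the analogue of a corpus cut at phone boundaries. Derivative features
use the conventional 2-frame regression over the frame sequence; a
duration-aware variant regressing against frame-center time is available
(`time_aware_deltas`) but measured slightly worse on this corpus, so the
conventional form is the default.

## What the synthetic corpus emulates — and what it does not

The built-in generator (`synth_cv()`, `build_corpus()`) produces
consonant–vowel tokens from a source–filter model: 20 ms silence pads, a
place-shaped noise-burst transient (5–15 ms), a formant transition
(30–60 ms) whose three resonators glide from consonant loci to vowel
targets, and a quasi-steady vowel (100–250 ms) excited by a glottal impulse
train at $f_0 \in [80, 220]$ Hz. Six stop classes {p, t, k, b, d, g} differ
by burst band (labial 300–1200, velar 1500–2600, alveolar 3500–7000 Hz),
second-formant locus, voicing (voiced stops carry pre-voicing; voiceless
stops are aspiration-excited over the first 60% of the transition, with the
first formant voiced-only — the long-VOT cue), against three vowels
{aa, ih, ah} with canonical formant targets.

Design choices the pipeline's behavior depends on, and their grounding:

* **Segment levels** (burst RMS 0.7, transition 0.9, vowel 1.0 before peak
  normalization): natural stop syllables have an intense but brief burst
  transient and a voiced transition within about 1 dB of the vowel. At
  these levels consonant-region frames carry intermediate energy at the
  theta frame scale — the contrast the $\alpha d \le E \le \beta d$ gate
  encodes. With a much weaker consonant the gate never fires and the
  nesting degenerates.
* **Vowel micro-variation** ($f_0$ declination ~15%, 1% jitter, 5% shimmer,
  6% formant drift): without it the synthetic vowel is *perfectly* steady,
  adjacent long-frame spectra become identical, and any segmentation that
  scatters short frames across the vowel scores spuriously well on CSE.
  Natural vowels are only quasi-steady.
* **Transient place cues** (distinct burst bands; the formant glide
  completes within ~20 ms of voicing onset): in natural stops the place
  information is concentrated at the release. This is precisely the
  structure a fixed 25 ms window smears and a variable frame isolates; with
  implausibly slow glides the comparison under test loses its subject.
* **Recording-noise floor** ($-50$ dB re peak): real captures never contain
  digital zero. Exact-zero silence produces degenerate (zero-variance)
  feature frames that make clean-trained emission models pathologically
  overconfident.

What the generator does **not** emulate: coarticulation beyond a linear
locus-to-target glide, speaker variability beyond $f_0$ and duration draws,
prosody, reverberation, or any natural-speech irregularity in the noise
classes ("stationary" is tilted Gaussian noise; "babble_like" sums eight
synthetic syllable streams). Properties demonstrated on this corpus — the
frame-allocation pattern, the CSE ordering of schemes, boundary stability
under noise — are statements about the algorithm under controlled,
favorable conditions, not measurements on natural speech.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes on one core: 100–200 tokens for the
segmentation and CSE properties, 1000 Monte-Carlo repetitions for the
random-segmentation reference on a 10-token subset, 20 probe stimuli for
the band scan, 50 tokens for noise stability, and a recognition benchmark
of 6 classes × (60 train + 24 test) tokens at three SNRs in two noise
kinds, repeated for three seeds. Corpus-scale studies of this method used
phone-aligned natural-speech corpora of several thousand tokens; none of
the absolute figures at desk scale are comparable to such results, only the
internal contrasts.

## Known limitations

* The nested reference assumes a single dominant syllabic event per token;
  running speech would require the phase partition to track multiple
  syllables, which the energy gate's global mean $d$ does not model.
* Frame energies are raw sums, so additive noise raises short, quiet frames
  proportionally more than long, loud ones; at low SNR this can move
  individual frames across the energy window and change which regions are
  re-segmented, even while the boundaries themselves barely move.
* The recognition advantage of variable frames is data-hungry: a
  variable-frame token contributes roughly a quarter as many feature
  vectors as the fixed grid, so at small training sizes the fixed-frame
  models are better estimated. The package's benchmark sizes sit near that
  regime; `noise_benchmark()` exposes the corpus sizes so the trade-off can
  be explored directly.
* CSE compares only *adjacent* frames; it rewards boundary placement, not
  parsimony, and two segmentations with different frame counts are compared
  through their mean adjacent distance only.

## A worked call

```{r example}
syl <- synth_cv(syllable_spec("p", "aa", seed = 7))
seg <- nvfs(syl$wave)
summary(seg)
cse(syl$wave, seg)
```

```{r plot, fig.height = 5}
plot(seg, wave = syl$wave)
```
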