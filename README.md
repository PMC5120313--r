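# nvfs — nested variable frame size speech segmentation

Speech front ends conventionally chop the signal on an external clock — a
25 ms window advanced every 10 ms — which smears stop-consonant bursts
(5–15 ms) and oversamples steady vowels (100–250 ms), a major source of
recognition errors in noise. `nvfs` implements an alternative in which the
signal's own amplitude envelope supplies the clock, and provides everything
needed to study it end-to-end on a built-in synthetic consonant–vowel
corpus: segmentation, an information-gain metric, features, and a
noise-robustness recognition benchmark.

## The method

For a waveform `s_r(n)`:

1. the Hilbert envelope `a(n) = |s_r(n) + i·H{s_r}(n)|` is extracted;
2. a zero-phase 3rd-order Butterworth bandpass isolates the **theta**
   (4–10 Hz) envelope oscillation; its instantaneous phase is split into
   four quadrants, and every quadrant crossing becomes a frame boundary;
3. frame energies `E_i = Σ s_r(n)²` are compared with their mean `d`:
   frames with `0.32·d ≤ E_i ≤ 0.8·d` — consonant and transition material,
   between the silence floor and the vowel plateau — are re-segmented at
   the quadrant crossings of the **low-gamma** (25–35 Hz) envelope
   oscillation.

The two-timescale composite (the *nested oscillatory reference*) tiles the
utterance with ~7–10 ms frames over bursts and transitions and 20–80 ms
frames over vowels. Segmentation quality is measured by the
**cochlea-scaled spectral entropy** (CSE): the mean Euclidean distance
between unit-norm 33-channel ERB spectra of adjacent frames — higher means
the boundaries capture more spectral change per frame.

The package also provides the standard baselines (fixed 25/10 ms grid,
random and reversed-order segmentations), variable-frame 39-dimensional
MFCC features, SNR-controlled noise mixing, and a left-to-right GMM-HMM
classifier (4 states, 5 mixtures per state) for isolated-syllable
recognition — plus a source–filter generator for labeled CV syllables
(6 stop consonants × 3 vowels) and synthetic noises, so no external speech
corpus is required.

## A worked example

```r
library(nvfs)

syl <- synth_cv(syllable_spec("p", "aa", seed = 7))   # a /pa/ token
seg <- nvfs(syl$wave)                                 # nested segmentation
seg
#> Nested variable frame size segmentation (theta -> low_gamma)
#>   8 frames over 0.214 s (5 secondary, 1 substituted regions)
#>   frame durations 5.6-79.8 ms (median 8.7)

head(as.data.frame(seg), 6)
#>   start  end    source
#> 1     0  138 secondary
#> 2   138  274 secondary
#> 3   274  414 secondary
#> 4   414  553 secondary
#> 5   553  643 secondary
#> 6   643 1919   primary

cse(syl$wave, seg)                                    # nested frames
#> <cse> 0.7216 over 8 frames (7 adjacent distances)
cse(syl$wave, ffsr_segment(length(syl$wave$samples), 16000))  # fixed grid
#> <cse> 0.3178 over 19 frames (18 adjacent distances)
```

The five short `secondary` frames cover the burst and formant transition of
the /p/ (the token's first ~40 ms of signal); the three long `primary`
frames cover the vowel. The nested segmentation's CSE of 0.72 against the
fixed grid's 0.32 says its boundaries extract more spectral change per
frame from the same token. `plot(seg, wave = syl$wave)` draws the waveform,
envelope and the quadrant-colored nested reference.

Higher-level experiment drivers: `cse_comparison()` (scheme-vs-scheme CSE
over a corpus), `band_scan()` (CSE ranking of all 30 ordered band pairs),
`noise_benchmark()` (clean-trained recognition at chosen SNRs and noise
kinds), `mix_at_snr()`, `synth_noise()`, `build_corpus()`.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/nvfs-cli.R synth   --output corpus/ --n 10 --seed 1
Rscript inst/cli/nvfs-cli.R segment --input corpus/cv_001_p.wav --output labels.tsv
Rscript inst/cli/nvfs-cli.R bench   --output results/ --seed 1
```

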