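---
title: "Measuring pronunciation distance from audio alone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pronunciation distance from audio alone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accdist)
```

## The problem

How foreign-accented is a speaker's pronunciation, compared to native
speech? Transcription-based answers (phonetic transcription plus an edit
distance) are accurate but expensive: transcribing is slow, error-prone,
and discretizes away gradient detail such as vowel quality, timing and
intonation. `accdist` implements an acoustic-only alternative: speakers
reading the same word list are compared directly on their audio, word by
word, and each speaker receives one score — their mean acoustic distance
to a set of native reference speakers.

## The measure

The pipeline has four stages.

**Segmentation.** Each recording is resampled to a common working rate
(default 11,025 Hz) and cut into words using externally produced
word-boundary annotations (forced-alignment output, consumed as Praat
TextGrids or `word,start,end` CSV). Cutting at word boundaries means only
corresponding stretches of speech are ever compared, and pauses,
false starts and other disfluencies between words never enter the
distance. Slices are half-open sample intervals
`[floor(start * rate), floor(end * rate))`, so a gap-free alignment
reconstructs the original region exactly.

**Features.** Every word is converted to mel-frequency cepstral
coefficients (MFCCs), the standard spectral-envelope representation of
speech. The recipe: pre-emphasis `H(z) = 1 - 0.97 z^-1` applied to the
whole word; 25 ms Hamming-windowed frames every 10 ms; periodogram power
spectrum (512-point FFT); 26 triangular filters spaced evenly on the mel
scale `2595 log10(1 + f/700)`; log; orthonormal DCT-II. Per frame we keep
cepstral coefficients 1–12, replace the 0th by the explicit log frame
energy (computed on the pre-emphasized, un-windowed frame), and append
delta and double-delta regression coefficients over a ±2-frame window with
edge frames replicated — 39 features per 10 ms frame. Dropping the 0th
cepstral coefficient makes columns 1–12 exactly invariant to global gain,
a property the test suite checks.

Several of these constants are conventions rather than prescriptions:
the filter count (26), FFT size (512), delta window (2) and energy
definition follow the HTK-lineage defaults that the 39-dimensional
recipe comes from, and all of them are overridable in `mfcc_config()`.

**Speaker normalization (CMVN).** Much of the frame-to-frame variance in
MFCCs reflects who is talking and through what microphone, not what is
said. Cepstral mean and variance normalization standardizes each of the
39 dimensions per speaker: `(c(i,t) - mean_i) / sd_i`, with the mean and
*population* (1/N) standard deviation pooled over all frames of all the
speaker's words. A convolutional channel (a fixed microphone filter) is
approximately an additive constant in the log-cepstral domain, so CMVN
removes it; it also removes per-speaker gain and dampens habitual
spectral tilt. Columns whose standard deviation is below 1e-10 are only
mean-subtracted, so silent-channel columns cannot blow up.

**Alignment and averaging (DTW).** Two renditions of the same word are
compared with dynamic time warping over the cumulative cost
`gamma(i,j) = d(i,j) + min(gamma(i-1,j-1), gamma(i-1,j), gamma(i,j-1))`,
where `d` is the Euclidean distance between 39-dimensional frames, and
the total `gamma(n,m)` is divided by `n + m` so long and short words are
comparable. No warping window or slope weights are used — the plain
three-move recurrence with unit weights. The frame cost is the *rooted*
Euclidean distance by default; a squared variant sits behind
`mfcc_config(squared_cost = TRUE)` because the two readings are both
defensible and the choice measurably changes the scale. Per-word
distances are averaged into a speaker-pair distance, and pair distances
are averaged over all reference speakers into the speaker's final score.

Word tokens are matched positionally: the 69-word elicitation paragraph
contains repeated words ("her" four times), so labels are disambiguated
in paragraph order (`her`, `her.1`, ...) and the intersection of
available tokens is used when a speaker is missing words (the count is
recorded in `n_words_used`).

### Baselines

Two deliberately crippled variants isolate the contribution of each
pre-processing stage: `segmentation_only` runs word-level DTW on raw,
un-normalized MFCCs, and `normalization_only` runs a single DTW over the
whole unsegmented recording of CMVN-normalized features. On both real and
synthetic data the full measure should correlate more strongly with
perceived accent than either baseline.

## The synthetic cohort

No recordings ship with the package. Instead `make_cohort()` generates a
fully seeded synthetic study: reference talkers drawn around one vowel
formant grid, and target talkers whose vowels are shifted in proportion
to a planted accent magnitude, written to disk in exactly the layout
`run_measure()` consumes.

What it emulates, and the defaults chosen:

- **Speakers.** 20 targets, 10 references. Each talker gets a pitch
  drawn uniformly from 100–200 Hz and a ±2% scatter of the vowel grid —
  ordinary between-talker variation.
- **Accent.** A target with magnitude `m` (default grid 0–1) has F1
  raised by `25% * m`, F2 lowered by `15% * m`, and syllable durations
  stretched by `30% * m`: a vowel-space compression plus timing change,
  the two dimensions of accent the measure is meant to pick up. Planted
  native-likeness ratings are `7 - 5.5 m` plus noise (sd 0.3), clipped
  to the 1–7 scale of a Likert questionnaire.
- **Words.** Eight hVd-style monosyllables ("heed", "hid", ...), each a
  source–filter vowel: an impulse train at the talker's (jittered) pitch
  through cascaded two-pole resonators at the formant targets. Renditions
  of the same word differ by ~2% jitter in pitch, formants and duration,
  as human repetitions do.
- **Recording nuisances.** Each speaker records through their own
  channel — gain 0.3–1.0, spectral tilt ±0.3 (first-order FIR), additive
  noise at 1–5% of signal RMS — and the pauses between words vary in
  length and half the time contain a filled-pause ("uh"-like) burst that
  lies outside the annotated word boundaries. Both nuisances are
  independent of the planted accent. They are what makes the study
  conditions honest: CMVN exists to remove the channel, segmentation to
  remove the disfluencies, and without them the baselines would be
  artificially competitive.

What it does **not** emulate: consonants (words are vowel nuclei with
on/offset ramps), coarticulation, prosody beyond a linear f0 ramp,
reverberation, or perceptual rating noise beyond additive Gaussian.
Passing tests on this cohort therefore show that the pipeline recovers
planted segmental and durational differences under channel and
disfluency nuisance — not that it reproduces any particular correlation
value on real archive recordings, which depend on data we cannot ship.

Two smaller synthetic experiments mirror the package's evaluation
statistics: `perturbation_experiment()` compares repeated renditions of a
two-syllable word against device-coloured, rising-intonation and
lengthened-syllable variants (all three should — and do — exceed the
normal-vs-normal rendition distance), and `hvd_experiment()` checks that
DTW distances over a 12-vowel grid correlate positively with Bark-scaled
(F1, F2) formant distances, the classic vowel-space geometry.

## Evaluation statistics

`evaluate_measure()` joins a distance table with ratings and reports the
Pearson correlation; given transcription-based distances (and optionally
mispronunciation counts) it adds an OLS regression of ratings on all
measures and Steiger's (1980) modified z for comparing the two dependent
correlations (ratings being the shared variable):
`Z = sqrt(n-3) (z12 - z13) / sqrt(2 - 2s)` with Fisher-transformed
correlations and the covariance term evaluated at the pooled correlation.
`classical_mds()` (Torgerson double centering, via `cmdscale`) embeds
vowel distance matrices for visualization, with axes sign-oriented so the
largest-magnitude loading is positive, and reports variance explained as
the kept eigenvalue share of the positive spectrum. The Bark transform
defaults to Traunmüller's formula `26.81 f / (1960 + f) - 0.53`
(Zwicker's available via `method = "zwicker"`).

## Numerical choices and degenerate inputs

- Filterbank outputs and frame energies are floored at `1e-10` before
  the log, so silent frames are finite and all-zero frames map to a
  constant vector.
- Words shorter than one 25 ms window are symmetrically zero-padded to
  one window (with a warning) so very short function words still yield a
  frame.
- `estimate_cmvn()` uses the population (1/N) standard deviation, so a
  speaker's own pooled normalized frames have variance exactly 1.
- DTW materializes the full cost matrix (words are short — typically
  20–60 frames) in compiled code; speaker pairs are independent, and
  reruns are bit-identical.
- Resampling is polyphase with the rational ratio of the two rates and
  the output trimmed/padded to `round(L * target / rate)` samples, so
  duration is conserved to within one sample.
- Reference-subset draws are uniform without replacement from an
  explicit seeded stream; no function touches the global RNG state.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
material at deliberately modest sizes — a 20-target/10-reference cohort
of 8 words each, 10–20 seeded repetitions of the perturbation
experiment, 10 repetitions per vowel of the 12-vowel grid — chosen so
the whole suite completes in about a minute while every statistic is
still comfortably stable across seeds. All sizes are arguments, and
scale linearly (cohort generation, feature extraction) or quadratically
(pair distances) if increased.

## Known limitations

- The measure compares like words; it needs word boundaries from a
  forced aligner or manual annotation, and does not do alignment itself.
- Channel robustness is partial: CMVN removes stationary convolutional
  coloration, but additive noise and nonstationary channel effects leak
  into the distances (the perturbation experiment quantifies this — the
  device condition scores well above the normal-vs-normal floor).
- Distances are relative, not absolute: scores depend on the reference
  set, the word list and the MFCC configuration, and should only be
  compared within one run.
- The synthesizer is a test instrument, not a speech synthesizer; its
  vowels are clean enough that correlations on synthetic cohorts run
  higher than one should expect on field recordings.
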