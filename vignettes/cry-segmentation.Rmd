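---
title: "Segmenting infant cry recordings: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting infant cry recordings: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryseg)
```

## The problem

A newborn cry recording made in a working hospital ward mixes the sounds a
diagnostic system actually wants — audible expiratory cries (`EXP`) and
vocalized inspirations (`INS`) — with background silence (`BKG`), adult
speech, monitor beeps and miscellaneous noise (`NOR`). Classical voice
activity detection with fixed energy/zero-crossing thresholds fails here:
thresholds that suit one bedside are wrong at the next, and energy alone
cannot tell a cry from a voice or an alarm. `cryseg` therefore combines a
*statistical* first pass (per-class GMM or HMM frame classification) with a
*signal-driven* second pass that re-estimates background thresholds per
recording and snaps segment boundaries to voicing and intensity landmarks.

## Stage 1: frame classification

### Features

The mono signal (stereo input is averaged) is high-pass emphasized with
`1 - alpha z^-1` (`preemphasis_alpha = 0.97`), framed at
`frame_len_ms = 30` / `overlap_ms = 21` (a 9 ms hop — the hop, not the
window, sets the label resolution), and Hamming-windowed. Per frame we
compute 12 mel cepstra over `n_filters = 26` triangular filters plus a
log-energy term; appending delta and acceleration coefficients
(`delta_window = 2`, regression form with edge replication) gives the
39-dimensional classifier input. Two recipes exist:

* **fft-mfcc** — cepstra from the raw power spectrum;
* **emd-mfcc** — cepstra from the sum of intrinsic mode functions 3–5 of
  an empirical mode decomposition of the *whole utterance* (sifting per
  frame would break IMF continuity across frame boundaries, so the
  decomposition runs once per recording before framing).

The cepstrum equation is implemented as the standard DCT-II over all `M`
filters, `c_n = sum_k log(S_k) cos[n (k - 1/2) pi / M]`, with natural
logs on filter energies; intensity uses `10 log10` (the dB convention).
The FFT size is the next power of two at or above the frame length. The
static vector is `c1..c12` plus log-energy so that statics + deltas +
accelerations give exactly 39 dimensions.

Intensity, zero-crossing counts and F0 — the side features driving
post-processing — are computed on the **un-emphasized** signal: the
dynamic thresholds emulate endpoint detection on the raw energy profile,
and pre-emphasis would distort exactly the low-frequency energy they
measure.

### Empirical mode decomposition

Sifting interpolates local maxima and minima with cubic splines
(extrema mirror-extended at both ends to curb end swings), subtracts the
envelope midline, and repeats until the candidate satisfies the
extrema/zero-crossing count criterion *and* the Huang standard-deviation
statistic falls below `sd_threshold = 0.2` (at most `max_sifts = 100`).
Neither test alone is reliable: SD alone accepts candidates whose counts
have not aligned on broadband signals; the count criterion alone can stop
a clean tone before the midline is removed. The decomposition telescopes,
so IMFs + residue reconstruct the input to machine precision — this
invariant is asserted in the tests.

### Classifiers

Each of the four classes gets its own model:

* **GMM** (`J` diagonal-covariance components, default configuration for
  fft-mfcc): EM from a seeded k-means initialization, variance floor
  `1e-6`, per-iteration log-likelihood guaranteed non-decreasing.
* **HMM** (`n_states = 4` left-to-right with self-loops, mixture
  emissions, default configuration for emd-mfcc): Baum–Welch over the
  labelled utterances of each class. The corpus-scale configuration of
  40 Gaussians is read as 10 per state; tests use smaller models, and
  both `J` and `n_states` (e.g. a 5-state variant) are plain arguments.

Decoding: a GMM bank labels each frame by maximum class likelihood
(ties broken by the fixed order `EXP < INS < BKG < NOR`; optional sliding
majority smoothing), an HMM bank by Viterbi through a composite network —
class models glued ergodically, uniform inter-class switch probability
discounted by `exp(-switch_penalty)`, rows renormalized. The penalty is
the smoothing knob: larger values make class switches rarer. Viterbi
correctness is property-tested against exhaustive path enumeration.

## Stage 2: post-processing

Given initial frame labels and the audio:

1. **Dynamic thresholds.** Silence statistics come from the earliest
   `silence_span_ms = 250` of frames the classifier called `BKG`
   (fallback: the minimum-mean-intensity window of that length — the
   thresholds stay defined even when the classifier finds no silence).
   Then `ZC_BKG = mean + 2 sd` of silence zero-crossings, and the
   intensity ladder `I1 = 0.03 (Imax - Imean) + Imean`, `I2 = 4 Imean`,
   `ITL = min(I1, I2)`, `INT_BKG = 5 ITL`. By default this multiplicative
   algebra operates on **linear frame energy** and converts back to dB
   (`linear_energy = TRUE`), which places `INT_BKG` about
   `10 log10(20) ≈ 13` dB above the silence floor — the regime the
   endpoint rules were designed for. Applied to dB values directly
   (`linear_energy = FALSE`, available for sensitivity analysis) the
   algebra degenerates for any recording whose silence intensity is
   negative in dB — i.e. all [-1, 1]-scaled audio — because `4 Imean`
   then undercuts every frame and no interval can ever test inactive.
2. **Marking.** Frames are indexed 1/0 by presence of an F0 estimate
   (autocorrelation peak over lags `rate/fmax .. rate/fmin`, band
   75–1000 Hz, normalized peak ≥ `voicing_threshold = 0.45`); the last
   frame of each voicing run and every local intensity minimum (first
   frame included when the contour rises away from it; optional 3-frame
   median pre-smoothing, off by default) are marked `2`, and the final
   frame always closes the last interval.
3. **Intervals.** Marks cut the frame range into intervals; an interval
   is *active* when its mean intensity reaches `INT_BKG` **or** its mean
   zero-crossing count reaches `ZC_BKG` (both comparisons `>=`). OR is
   chosen over AND so that unvoiced, high-ZCR cry fractions stay active.
4. **Final decision.** Activity indexes are concatenated onto the initial
   labels (`EXP1`, `NOR0`, …); maximal runs of equal composite labels get
   mean intensity and F0 min/max/mean attached and pass through the rule
   table: inactive runs become `BKG`; `EXP1`/`INS1` keep their class;
   voiced `NOR1`/`BKG1` runs are rescued into `EXP` (mean F0 in
   `exp_band = 250–1000` Hz, which takes precedence) or `INS`
   (`ins_band = 100–800` Hz), otherwise `NOR`.

Three guards temper the rescue, each motivated by the acoustics of the
ward rather than tuned to any test outcome:

* **No voicing, no overturn** — an active run without a single F0
  estimate keeps the classifier's class; there is no frequency evidence
  to argue with it.
* **Flat F0 is a beep** — runs whose F0 spread is below
  `min_f0_range_hz = 20` go to `NOR`: monitor alarms hold a constant
  fundamental, cry phonation never does.
* **Speech pitch without cry intensity stays NOR** — runs with mean F0 in
  `speech_band = 100–300` Hz are rescued only if their mean intensity is
  within `speech_margin_db = 6` dB of the recording's own confident cry
  runs; the crying newborn is the closest, loudest source, so adult
  speech sits well below that reference. With no confident cry run in
  the recording the guard is conservative and keeps such runs `NOR`.

All band edges, margins and threshold constants are arguments, not
constants. Segment times are half-open `[start, end)` seconds; frame `i`
(1-based) contributes the hop cell `[(i-1) hop, i hop)`, so tracks and
per-frame labels convert losslessly in both directions.

## The synthetic corpus

Clinical cry corpora are private, so the generator in this package *is*
the study material for tests. It is a seeded additive-harmonic
source-filter sketch: expiratory cries are harmonic series (1/h rolloff)
with falling F0 contours drawn from 380–650 Hz, 0.5–1.2 s, with 1% pitch
jitter and 5% amplitude shimmer under a raised-cosine envelope;
vocalized inspirations are shorter (0.2–0.5 s) bursts at 140–230 Hz;
speech is a 100–300 Hz harmonic with 4 Hz syllabic amplitude modulation;
beeps are fixed-frequency tones (800–1500 Hz); background is low-level
white noise, and `NOR` events are gated broadband bursts. Scene
composition interleaves 2–4 cry cycles with background gaps and
occasional interference. Default scene rate is 16 kHz (44.1 kHz
available); the test suite renders at 8 kHz, which keeps every F0 of
interest far below Nyquist while making the suite fast. Durations were
chosen once as plausible desk-scale values and are stated here as the
package's conditions.

What the generator does **not** emulate: formant structure and its
developmental variation, dysphonation and hyperphonation in pathological
cries, reverberation, overlapping simultaneous sources, and microphone
handling noise. Passing tests therefore demonstrate algorithmic
correctness and the intended interplay of the two stages — not clinical
performance. The headline detection rates achievable on a real ward
corpus cannot be reproduced from synthetic scenes, and the package makes
no such claim.

## Numerical choices and degenerate inputs

* Intensity uses a floor `eps = 1e-10` inside the log, so silent frames
  score `-100` dB instead of `-Inf`; filterbank energies are floored at
  `1e-12` before the log.
* Zero crossings treat exact zeros as positive, so a zero-grazing signal
  is counted consistently.
* EM and Baum–Welch are deterministic given their seed (k-means
  initialization with a private RNG stream that never disturbs the
  caller's RNG state); collapsed mixture components are floored and
  reported with a warning.
* Viterbi errors out, naming the frame, if every state is impossible;
  a tie anywhere resolves to the lowest state index.
* Signals shorter than one frame refuse to frame; fewer than two maxima
  or minima refuse to sift (a monotone residue ends the decomposition);
  a recording shorter than the silence span uses all frames for the
  thresholds, with a warning.
* Interval construction requires the final frame to be a boundary (the
  combination step guarantees it); a boundary at frame 1 opens rather
  than closes the first interval, matching the worked reference tables.

## Evaluation

Scoring is frame-level, one class versus the rest: `TPR = TP/(TP+FN)`,
`FPR = FP/(FP+TN)`, `FNR = FN/(TP+FN)` in percent, plus overall accuracy
(correct frames over all frames). Annotation labels collapse onto the
four modelled classes (`INSV` to `INS`; silent inspirations, faint cries,
babbling, speech, beeps and noise all to `NOR`) before scoring. An empty
reference class reports `NA` rates, never zero. Cross-validation splits
by recording — never by frame — with fold sizes differing by at most one,
deterministic under a seed; the number of repetitions is an argument of
the surrounding analysis, not hard-wired.

## Problem sizes used in the tests

The suite trains GMM banks with 4 components per class on 6 rendered
scenes at 8 kHz, decodes held-out scenes, and exercises the HMM path with
2-state models on a 2-scene corpus; EMD properties are checked on
4096-sample signals, Viterbi against exhaustive enumeration on sequences
of length ≤ 8 with ≤ 4 states, transition-matrix recovery on 50 simulated
sequences of length 200, and the label-noise robustness property on 50
seeded scenes. These sizes were chosen as the smallest at which each
property is meaningfully exercised.

## Known limitations

* The post-processing rule table is a documented default, not a claim
  about any particular annotator's final-decision rule; its bands are
  expected to need adjustment for corpora with unusual pitch ranges
  (e.g. extremely preterm infants).
* EMD runs per utterance; very long recordings pay a super-linear spline
  cost and may warrant block-wise decomposition, which the package does
  not implement.
* The composite decoding network shares one switch penalty across all
  class pairs; class-pair-specific transition priors (e.g. EXP to INS
  being likelier than EXP to BIP-like noise) are not modelled.
* Only PCM WAV input (8/16/24-bit) is supported, and stereo handling is
  limited to channel averaging.
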