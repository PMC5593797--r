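# cryseg

Automatic segmentation of newborn cry recordings into their diagnostically
useful units: audible **expiratory cries (EXP)**, **vocalized inspirations
(INS)**, **background silence (BKG)** and **other acoustic activity (NOR —
speech, machine beeps, noise)**. Cry-based diagnostic systems need clean
expiratory and inspiratory episodes as input; recordings made in real
neonatal wards are anything but clean, and fixed-threshold voice activity
detection fails there. `cryseg` implements a two-stage alternative for
researchers working on infant-cry analysis.

## Method

**Stage 1 — statistical frame classification.** The mono, pre-emphasized
(`1 − 0.97 z⁻¹`) signal is cut into 30 ms frames with a 9 ms hop, Hamming
windowed, and described by a 39-dimensional vector per frame: 12
mel-frequency cepstra

&nbsp;&nbsp;&nbsp;&nbsp;Mel(f) = 2595 log₁₀(1 + f/700),&nbsp;&nbsp;
c_n = Σ_k log(S_k) cos[n(k − ½)π/M]

plus log-energy, with delta and acceleration coefficients. Cepstra are
computed either from the raw spectrum (FFT-MFCC) or from the sum of
intrinsic mode functions 3–5 of an empirical mode decomposition
(EMD-MFCC), which isolates the cry-relevant mid-band. One Gaussian mixture
model (or left-to-right hidden Markov model with mixture emissions) is
trained per class by EM/Baum–Welch; frames are labelled by maximum
likelihood or by Viterbi decoding through an ergodic composite network of
the class models.

**Stage 2 — post-processing (the point of the package).** Per-recording
dynamic thresholds are estimated from the frames the classifier itself
called background, in the style of Rabiner–Sambur endpoint detection:

    ZC_BKG  = mean(ZCR_sil) + 2 sd(ZCR_sil)
    I1 = 0.03 (Imax − Imean) + Imean;  I2 = 4 Imean
    ITL = min(I1, I2);  INT_BKG = 5 ITL

Frames are then indexed by voicing (does an autocorrelation F0 estimate
exist?), voicing-run transitions and intensity local minima; the marks cut
the recording into fine intervals whose mean intensity and zero-crossing
rate are compared against the thresholds. Interval activity is merged with
the initial class labels into composite labels (`EXP1`, `NOR0`, …), and a
rule table makes the final decision: inactive runs become background,
confident cry runs keep their class, and voiced active runs the classifier
missed are rescued into EXP/INS by their F0 statistics — with guards that
keep constant-F0 machine beeps and low-intensity speech-pitch runs out of
the cry classes. The result is a tightened, corrected segment track.

Because clinical cry corpora are private, the package ships a seeded
synthetic scene generator (harmonic cries with falling F0 contours,
vocalized inspirations, speech, beeps, noise) with exact ground-truth
labels, so every stage is testable end to end.

## Worked example

```r
library(cryseg)

corpus <- make_training_corpus(8, seed = 7, sample_rate_hz = 16000)
feats  <- collect_training_features(corpus, kind = "gmm")
bank   <- train_classifier_bank(feats, kind = "gmm", J = 8, seed = 1)

scene  <- render_scene(random_scene_spec(901, sample_rate_hz = 16000))
res    <- run_full(scene$audio, bank, verbose = TRUE)
#> thresholds: ZC_BKG=270.046 INT_BKG=-13.329 (source: initial-BKG)

ref <- collapse_to_classes(track_to_frame_labels(
  scene$labels, res$initial$n_frames, 0.030, 0.009))
ev <- evaluate_frames(ref, res$frame_labels)
dplyr::select(ev$per_class, class, TPR, FPR, FNR)
#> # A tibble: 4 × 4
#>   class   TPR   FPR   FNR
#>   <chr> <dbl> <dbl> <dbl>
#> 1 EXP    97.2 0.531  2.79
#> 2 INS    94.5 1.02   5.48
#> 3 BKG    98.2 2.68   1.81
#> 4 NOR    91.5 0.491  8.46
```

The logged thresholds are the recording's own background statistics:
`ZC_BKG` in crossings/frame, `INT_BKG` in dB. The per-class table gives
one-vs-rest detection rates in percent against the scene's ground truth —
here 97% of expiratory frames are recovered with 0.5% false positives,
and the interference events (speech, beeps) stay out of the cry classes.
`res$track` is a tibble of final segments; `autoplot(res$track)` draws
them.

A command-line front end with `synth` / `train` / `segment` / `refine` /
`evaluate` / `crossval` subcommands is installed at
`system.file("scripts", "cryseg", package = "cryseg")`.

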