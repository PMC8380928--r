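---
title: "Methods: simulating and analysing roving-oddball MMN experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing roving-oddball MMN experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rovingmmn)
```

## The scientific problem

The mismatch negativity (MMN) is a negative deflection of the auditory
event-related potential (ERP) elicited when an infrequent *deviant* sound
interrupts a regularity established by repeated *standards*. Its amplitude
indexes how strongly the brain registers an auditory change, and comparing
the MMN across the two directions of the same physical change (A-among-Bs
versus B-among-As) exposes *perceptual asymmetries*. In a roving-standard
design, the two stimuli alternate in trains of repeated tokens, so each
stimulus serves as its own identity-matched control: the deviant ERP for
stimulus X is compared with the standard ERP for the *same* stimulus X,
eliminating any confound from acoustic differences between the stimuli.

This package implements the full computational chain of such an
experiment — stimulus synthesis, sequence construction, ERP preprocessing,
difference-wave quantification, and mixed-effects analysis — together with
a synthetic-EEG generator, so that every stage can be verified on data
with known ground truth.

## Stimuli and psychoacoustic metrics

Two stimulus domains are supported by one synthesis engine
(`synthesize_complex()`):

* **Inharmonic tone complexes**: 15 components, the first at 500 Hz and
  each subsequent one 1.15 times higher (geometrically spaced, hence no
  common fundamental), formant-weighted, 5-ms linear onset/offset ramps,
  peak-normalized. These are spectrally as rich as vowels but not
  confusable with speech.
* **Vowel-like fixtures** (`synthesize_vowel_fixture()`): a harmonic
  source with the same formant weighting, optionally preceded by a 150-ms
  noise burst standing in for a fricative onset; the `carrier_onset`
  metadata field (150 ms with the prefix) tells downstream epoching where
  the vowel begins. These fixtures stand in for natural recordings, which
  are outside the package's scope.

Each domain yields four stimuli from one configuration: a *spectral* pair
(220 ms, focal [a]-like 864/1287/2831 Hz versus diffuse [e]-like
755/1646/2710 Hz formants) and a *durational* pair (180 versus 360 ms,
both [e]-like). "Prominent" denotes the focal spectrum or the long
duration.

Formant "filtering" is per-component spectral weighting: the magnitude of
a cascade of three analog two-pole resonators evaluated at each component
frequency (`formant_weights()`). For purely tonal sources this is exactly
equivalent to filtering but deterministic and alias-free. Formant
bandwidths default to 80/120/160 Hz, conventional speech-synthesis
values. Initial phases are zero by default so outputs are bit-for-bit
reproducible; peak normalization is applied after ramping, i.e., the
normalization contract holds on the final waveform.

Psychoacoustic distances (`hz_to_bark()`, `focalization_distance()`,
`spectral_jnd_distance()`, `duration_jnd_distance()`):

* Bark conversion defaults to Traunmüller
  ($z = 26.81 f/(1960+f) - 0.53$), with Zwicker and Schroeder selectable.
  The conversion formula is exposed rather than hidden because published
  focalization values for comparable stimuli are not always reproducible
  from any single standard formula; users should know which one they get.
* Spectral distance is the Euclidean norm of the three per-formant Bark
  differences divided by a 0.3-Bark discrimination threshold.
* Durational distance counts cumulative Weber steps,
  $\ln(d_{max}/d_{min}) / \ln(1 + \theta/d_{ref})$ with a 5-ms threshold
  at a 90-ms reference. The log-ratio form is used because a single
  linear threshold cannot express a duration JND consistently across a
  doubling; under it the 180/360-ms pair is 12.8 JND apart while the
  formant pair is about 6 JND apart.

## The roving-standard sequence

`generate_sequence()` builds one block: a lead-in of 8 tokens of stimulus
A, then strictly alternating trains of B and A (the first train is B — an
initial A-train would be indistinguishable from the lead-in), with train
lengths drawn from {4..8} such that each length occurs exactly 20 times
per stimulus, in seeded random order. This yields 608 A-tokens, 600
B-tokens, 1208 total; at the 1.09-s stimulus onset asynchrony a block
lasts 22 minutes. Pseudorandomization imposes only the length-histogram
constraint; no additional restrictions (such as forbidding repeated
lengths) are applied.

Roles follow within-train position (`assign_roles()`): position 1 is the
deviant, the last two positions are standards, everything else is filler.
Lead-in tokens are tagged `lead_in` and never enter averaging — the
conservative choice, since the regularity they establish precedes the
first role-defined train. The first deviant of the block is retained, by
the literal position-1 rule. Trains shorter than 3 are rejected because
deviant and standard roles would overlap.

## The synthetic EEG generator

`simulate_recording()` renders an event list into a continuous
multichannel recording in microvolts:

* **Base ERP**: every event adds a configurable sum of Gaussian
  components time-locked to its carrier onset, identical for deviants and
  standards (so it cancels exactly in the difference wave).
* **MMN injection**: deviant events additionally receive the MMN
  component configured for their stimulus: either a Gaussian bump
  (SD 25 ms, centred mid-window — the realistic default) or a flat
  rectangle spanning the 100-ms analysis window. The rectangle option
  exists because its windowed area is exactly *amplitude × 100 µV·ms*,
  making end-to-end checks analytic. Change onset is 0 ms for spectral
  deviants and the short-stimulus duration (180 ms) for durational
  deviants, whose deviance only becomes detectable when the short
  stimulus would have ended.
* **Topography**: scalar per-channel weights (frontal 1.0, central 0.75,
  parietal 0.45 by default), encoding the frontally maximal MMN
  distribution. No forward head model is used — scalar weights are
  sufficient to exercise every downstream stage, and biophysical realism
  is a non-goal.
* **Noise**: per-channel independent $1/f$ noise (FFT-shaped white noise,
  exponent 1, RMS 10 µV by default), added independently of event roles.
* **Artifacts**: `inject_artifacts()` adds 50-ms supra-threshold
  transients to a seeded random fraction of epochs and logs the affected
  events, so rejection behaviour is verifiable against ground truth.

A single master seed fans out to per-purpose child seeds
(`child_seed()`), so enabling artifacts does not shift the noise stream.
Recordings round-trip through EDF+ (`write_edf()`/`read_edf()`) with
events carried as annotations; amplitudes are 16-bit quantized within the
configured physical range (error at most range/2¹⁵).

The generator emulates: event-locked ERPs, a condition-dependent MMN with
frontal topography, 1/f background noise, and occasional large artifacts.
It deliberately does **not** emulate: eye blinks or cardiac artifacts,
inter-trial latency jitter, volume-conduction correlations between
channels, or non-stationary noise. Passing tests therefore demonstrate
the correctness of the *pipeline machinery* on data obeying the stated
generative model, not robustness to every pathology of real EEG.

## ERP preprocessing

`process_block()` chains the standard steps, each exposed individually:

* **Band-pass 0.2–40 Hz** (`bandpass()`): zero-phase Butterworth cascade
  (2nd-order high-pass, 4th-order low-pass, each applied forward and
  backward). A linear-phase FIR realization of a 0.2-Hz edge at 3000 Hz
  would need a kernel tens of thousands of taps long; the
  forward-backward IIR cascade is the field-standard alternative and
  meets the same contracts — no group delay (an impulse's peak does not
  move), unity passband gain at 10 Hz within 0.5 dB, DC removed exactly,
  far more than 20 dB attenuation at 100 Hz.
* **Downsampling to 300 Hz** (`downsample()`): plain decimation, with the
  prior 40-Hz low-pass as anti-alias filter; event indices rescale
  exactly. Non-integer ratios are rejected.
* **Epoching** (`epoch()`): half-open window [−100, 800) ms relative to
  *carrier* onset (vowel onset for syllables, file onset for tones),
  giving 270 samples at 300 Hz; the sample at t = 0 belongs to the
  post-stimulus side.
* **Baseline correction** (`baseline_correct()`): subtracts the mean over
  [−100, 0) per trial and channel.
* **Rejection** (`reject()`): a trial is removed when its absolute
  amplitude reaches 50 µV on *any* channel ("under 50 µV" is strict, so
  exactly 50 µV is rejected). Whole-trial rejection across channels is
  the conservative reading of a per-epoch threshold.
* **Averaging** (`average_epochs()`) by stimulus × role, then
  **Savitzky–Golay smoothing** (`savgol_smooth()`, order 1, 21 samples)
  of difference waves. An order-1 midpoint estimate equals the centred
  moving average at interior points; edges use least squares on the
  truncated window rather than reflection padding, which keeps linear
  trends exact everywhere.

## MMN quantification

`difference_wave()` subtracts the standard ERP from the deviant ERP of
the *same* stimulus and refuses mismatched labels — the identity-matching
guarantee of the roving design. `auc()` integrates the (smoothed)
difference wave over the analysis window by the trapezoid rule on the
300-Hz grid, with window endpoints snapped to the nearest sample (at
300 Hz the 150/250/330/430-ms endpoints fall exactly on samples). The
area is signed — an MMN is negative — and `window_for()` encodes the
window rule: 150–250 ms post carrier onset for spectral deviants,
330–430 ms for durational deviants (change onset 180 ms plus
150–250 ms). `build_mmn_table()` assembles one row per participant ×
domain × dimension × deviant × channel over the 3×3 grid
F3/Fz/F4, C3/Cz/C4, P3/Pz/P4 — the grid implied by a Laterality ×
Anteriority contrast structure; it is configurable.

## The statistical model

`fit_mmn_model()` fits, by REML via lme4/lmerTest,

$$\mathrm{AUC} \sim \mathrm{Dev} + \mathrm{Dim} + \mathrm{Dom}
  + \mathrm{Lat}_1 + \mathrm{Lat}_2 + \mathrm{Ant}_1 + \mathrm{Ant}_2
  + \mathrm{Dev{:}Dim} + \mathrm{Dev{:}Dom} + \mathrm{Dim{:}Dom}
  + \mathrm{Dev{:}Dim{:}Dom} + (1 + \mathrm{Dim} + \mathrm{Dev} \mid
  \mathrm{participant})$$

with deviation codes ±0.5 for Domain (−speech, +tone), Dimension
(−duration, +spectrum) and Deviant (−prominent, +non-prominent), so each
main effect estimates a mean difference and the intercept the grand mean;
±0.5 was chosen over ±1 for that interpretability. Laterality uses
left −0.5 / right +0.5 / midline 0 plus a centred midline-versus-lateral
contrast; Anteriority uses centred frontal-minus-central and
parietal-minus-central contrasts. All columns are mean-centred on a
balanced design; the twelve fixed-effect terms mirror the conventional
reporting table. Degrees of freedom use the Satterthwaite approximation;
a residual-df option exists for replicated simulation studies, where the
terms under test carry around a thousand df and the two methods agree to
the third decimal while the residual path is several times faster.
Singular random-effects fits are flagged in the output, never hidden. The
mixed-model *solver* is deliberately delegated to lme4 — the bespoke
content is the contrast coding, cell-mean machinery and simulation
harness, and the solver is cross-checked against an OLS oracle on
balanced designs in the tests.

`estimate_cell_means()` produces model-estimated domain × dimension ×
deviant means (channel contrasts integrate to zero over the grid) with
normal-approximation 95% CIs from the fixed-effects covariance, and
`asymmetry_flags()` applies the CI-exclusion decision rule: two deviant
directions are called asymmetric when one deviant's 95% CI excludes the
other's estimated mean.

## Two simulation scales, and why

Verification uses two generators on purpose:

1. **Waveform scale** (`simulate_recording()` through `process_block()`):
   exercises every signal-processing stage. Zero-noise runs with the
   rectangle MMN make the entire chain analytic: an injected −2 µV
   rectangle must come out as −200 µV·ms times the channel weight,
   exactly, at every channel. For these analytic runs the band-pass and
   smoothing stages are disabled (`filter = FALSE`, `smooth = FALSE`),
   since any filter necessarily redistributes a rectangle's edge energy;
   those stages are verified by their own spectral contracts instead.
2. **Study scale** (`simulate_mmn_table()`): generates the AUC table
   directly from the linear model the analysis assumes (cell means +
   additive channel offsets + participant random intercept and
   Dimension/Deviant slopes + residual noise). Replicated
   simulate-and-refit studies (`run_recovery_study()`) then check
   parameter recovery, type-I calibration of the three-way interaction
   test, and asymmetry-detection power at the full design size — 16
   participants per domain, hundreds of replicates — which would be
   computationally absurd through the waveform generator (one full block
   is 22 minutes of 31-channel, 3000-Hz signal).

Study-scale defaults: cell means of −95/−17 µV·ms for the
prominent/non-prominent deviants in the speech-spectral cell and around
−44 to −48 µV·ms in the three symmetric cells; channel offsets encoding
the frontal-negative, parietal-positive gradient; random-effect SDs of
40 (intercept) and 30 (each slope) and residual SD 90 µV·ms. The noise
level is deliberately generous: it was calibrated once, analytically, so
that detecting the built-in asymmetry at 16 participants per domain has
power near 1 — the recovery studies are meant to be sharp tests of the
machinery, where a failure indicates a defect rather than sampling luck.
At these settings the per-participant deviant-difference SD in one cell
is about 33 µV·ms, giving a cell-mean-difference z of roughly 6 for the
78-µV·ms built-in asymmetry. A replicated bias check at a few hundred
replicates cannot resolve bias below Monte-Carlo noise, so the recovery
study reports Monte-Carlo standard errors alongside biases and judges
small-truth terms against the noise floor rather than a vanishing
relative band.

## Numerical choices and degenerate inputs

* Window endpoints snap to the nearest sample before integration; at
  300 Hz all standard endpoints are exact grid points.
* Rejection at exactly threshold rejects (strict "under" retention).
* Empty averaging cells and all-rejected blocks raise errors naming the
  cell; out-of-window events are skipped with a logged warning; events
  overrunning the record are an error at simulation time.
* EDF padding to whole one-second records stores the true sample count in
  the header so round-trips restore exact length; WAV uses float32 by
  default so audio round-trips are exact to single precision.
* Train lengths of 1–2 are rejected (roles would overlap); `sample.int`
  is used for shuffling so length-1 pools do not trigger R's
  `sample()`-on-a-scalar pitfall.

## Known limitations

* The vowel fixtures are synthetic stand-ins, not resynthesized natural
  speech; conclusions about real vowel recordings require real stimuli.
* The generator's independence of channels and stationarity of noise are
  idealizations; robustness to correlated or non-stationary noise is not
  tested.
* The statistical machinery assumes the balanced design the paradigm
  produces; heavily unbalanced real data (e.g., after aggressive
  rejection) will work but the OLS equivalences used as oracles no
  longer hold exactly.
* With only a handful of participants the random-slope model is often
  singular; the fit reports this and `lmm_intercept`/`ols` methods are
  available for small demos.
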