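# rovingmmn

Simulation and analysis of auditory **mismatch negativity (MMN)**
experiments built on the **roving-standard (roving-oddball) paradigm**,
for EEG/ERP researchers who want a fully verifiable pipeline: every stage
can be run against synthetic data with known ground truth before it ever
touches a real recording.

The package covers the whole chain:

1. **Stimuli** — inharmonic tone complexes (15 components from 500 Hz,
   ratio 1.15, formant-weighted) and vowel-like harmonic fixtures with a
   fricative-like 150-ms prefix; WAV I/O; psychoacoustic metrics (Bark
   conversion, formant focalization, spectral and durational distances in
   just-noticeable-difference units).
2. **Paradigm** — constrained roving-standard sequences: an 8-token
   lead-in, then 100 alternating trains per stimulus with lengths 4–8,
   each length exactly 20 times, SOA 1.09 s; deviant = first token of a
   train, standards = last two tokens.
3. **Synthetic EEG** — 31-channel recordings with event-locked ERPs, a
   condition-specific injectable MMN (frontal-maximal topography), 1/f
   noise, supra-threshold artifacts; EDF+ I/O with event annotations.
4. **ERP processing** — zero-phase 0.2–40 Hz band-pass, decimation to
   300 Hz, epoching −100..800 ms around carrier onset, baseline
   correction over [−100, 0) ms, 50-µV rejection, averaging,
   Savitzky–Golay smoothing (order 1, 21 samples).
5. **MMN quantification** — identity-matched difference waves
   (deviant X minus standard X, never across stimuli) and signed
   trapezoidal area in a 100-ms window starting 150 ms after change
   onset: 150–250 ms for spectral deviants, 330–430 ms for durational
   deviants (change onset = 180-ms short-stimulus duration).
6. **Statistics** — a deviation-coded (±0.5) linear mixed-effects model

   `AUC ~ Deviant * Dimension * Domain + Laterality (2) + Anteriority (2)
   + (1 + Dimension + Deviant | participant)`

   with Satterthwaite tests, model-estimated cell means with 95% CIs, a
   CI-exclusion asymmetry decision rule, and replicated
   parameter-recovery / type-I / power studies via a study-level
   generator.

## Worked example

Psychoacoustics and paradigm bookkeeping:

```r
library(rovingmmn)

focalization_distance(stimulus_formants("a"))   # 2.424076 Bark (focal)
focalization_distance(stimulus_formants("e"))   # 4.78228  Bark (diffuse)
spectral_jnd_distance(stimulus_formants("a"), stimulus_formants("e"))
                                                # 5.995067 JND
duration_jnd_distance(180, 360)                 # 12.8201  JND

plan <- roving_plan(seed = 7)
ev <- generate_sequence(plan)
table(ev$stimulus)                # fa220: 600, fe220: 608  (1208 total)
total_duration(ev, plan)$minutes_rounded        # 22
```

An analytic end-to-end check — zero noise, a rectangular −2 µV MMN over
the analysis window, filtering and smoothing off — must return exactly
−200 µV·ms scaled by each channel's topography weight:

```r
cfg <- run_config(n_per_domain = 1, lead_in = 2, train_lengths = 4:5,
                  reps_per_length = 1, channels = c("F3", "Fz", "Cz", "Pz"),
                  mmn_shape = "rect", noise = noise_spec(1, 0),
                  mmn_amplitudes = transform(default_mmn_amplitudes(),
                                             amplitude_uv = -2),
                  filter = FALSE, smooth = FALSE, seed = 3)
rec <- simulate_block(cfg, "p1", "speech", "spectral")
process_block(rec, cfg, channels = c("F3", "Fz", "Cz", "Pz"))$mmn[
  , c("stimulus", "channel", "auc_uv_ms")]
#>   stimulus channel auc_uv_ms
#> 1    fa220      F3      -200
#> 2    fa220      Fz      -200
#> 3    fa220      Cz      -150
#> 4    fa220      Pz       -90
#> ...
```

(F3/Fz carry weight 1.0, Cz 0.75, Pz 0.45.) The negative area is the
mismatch negativity; at noisy, realistic settings the same chain feeds
`fit_mmn_model()` and `asymmetry_flags()`.

The `analysis/` directory holds the numbered workflow scripts
(`01_stimuli.R` … `06_recovery.R`) that run the whole study at demo scale
and write their tables under `results/`.

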