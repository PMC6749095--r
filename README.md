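# incluflux

Quantitative-microscopy analysis of large protein inclusions — such as the
inclusion bodies (IBs) formed by polyglutamine-expanded huntingtin
fragments in budding yeast — as **mobile, gel-like compartments that
continuously exchange material with the cytoplasm**. The package provides
the four analytical arms of that characterisation, plus a seeded
synthetic-microscopy generator that supplies ground truth for every stage,
so the whole pipeline is testable without any imaging data.

**Who it is for.** Cell biologists and image analysts quantifying
biomolecular condensates / protein aggregates in time-lapse and z-stack
fluorescence microscopy, and anyone needing a calibrated, fully synthetic
test bed for single-particle tracking and flux estimators.

## What it computes

1. **Single-particle motion.** Spot enhancement by a scale-normalised
   Laplacian-of-Gaussian filter; single-target linking by exact dynamic
   programming under the published cost weights (intensity 80%, intensity
   variation 20%, movement 40%, center 0%, max displacement 10 px);
   per-track mean squared displacement over lags 1–16 with all overlapping
   intervals. The anomalous-diffusion exponent α is the slope of
   log₁₀ MSD vs log₁₀ Δt (MSD ∝ Δt^α; α = 1 free diffusion, α > 1
   directed); the diffusion coefficient comes from the zero-intercept fit
   MSD = 4 D Δt. Groups are compared by Welch's t test.
2. **Morphometry.** Threshold segmentation of z-stacks at 1.2× the mean
   cytoplasmic intensity; circularity CR = 4π·area/perimeter² from a
   sub-pixel contour; intensity-weighted aspect ratio; apparent volume;
   IB / small-particle / cluster-like-inclusion classification (area
   cutoff 0.01 µm²); prevalence summaries and the chance-overlap
   probability π((d_IB + 2 d_AP)/2)² / available area.
3. **FRAP.** Bleach-recovery quantitation at a 1.4× threshold (integrated
   intensity = area × mean, equivalent-circle diameter ratio), plus a
   simulator realising interior-mixing vs surface-accretion vs no-exchange
   regimes, separated by a shell/core intensity statistic.
4. **Photoconversion pulse-chase.** A two-pool (cytoplasm ⇄ IB) two-colour
   kinetic model with synthesis, degradation and cell-division dilution
   (daughter = 70% of mother; the IB stays with the mother); exponential
   photobleaching calibration and correction; 1.5×-threshold union masks;
   turnover summaries (time of maximum, percent drop); dilution
   predictions (1/factor); and recovery of k_in, k_out, k_deg by refitting
   the model.

## Worked example

```r
library(incluflux)

# 23 freely diffusing particles, D = 0.059 um^2/s, imaged at 32 fps
tracks <- simulate_ensemble(motion_model("brownian", 0.059),
                            n_tracks = 23, n_frames = 300,
                            frame_interval = 1/32, seed = 1)
est <- motion_table(tracks, max_lag = 16)
sprintf("mean alpha = %.3f +/- %.3f (SEM, n = 23)",
        mean(est$alpha), sd(est$alpha)/sqrt(23))
#> "mean alpha = 0.993 +/- 0.018 (SEM, n = 23)"
sprintf("mean D = %.4f um^2/s (generator: 0.059)", mean(est$D_um2_s))
#> "mean D = 0.0611 um^2/s (generator: 0.059)"
min(est$r2)
#> 0.991

# inclusion-body-like motion: diffusion plus persistent drift
ib <- simulate_ensemble(motion_model("directed", 0.005, drift_speed = 0.2,
                                     drift_persistence = 1),
                        23, 300, 1/32, seed = 2)
cmp <- compare_groups(motion_table(ib)$alpha, est$alpha)
sprintf("IB alpha %.2f vs small-particle alpha %.2f: t = %.1f, p = %.1e",
        cmp$mean_a, cmp$mean_b, cmp$t, cmp$p)
#> "IB alpha 1.20 vs small-particle alpha 0.99: t = 9.0, p = 2.0e-11"

predict_dilution(3.7)$percent   # fluorescence left after 3.7x dilution
#> 27.03
```

The mean exponent of the diffusing ensemble sits at 1 (free diffusion)
with every per-track log-log fit essentially linear; the drift-containing
ensemble is cleanly superdiffusive; and a 3.7-fold dilution predicts 27%
of the original intensity remaining.

## Analysis workflow

The `analysis/` directory holds the five narrative drivers, run from the
repository root in order; each prints what it finds and writes its tables
under `results/`:

| script | writes |
| --- | --- |
| `01_simulate_tracks.R` | ground-truth trajectory ensembles (CSV + YAML) |
| `02_track_and_msd.R` | tracker validation, per-track α/D estimates, group test |
| `03_morphometry.R` | object table, shape/volume summaries, prevalence, overlap |
| `04_frap.R` | FRAP time courses, regime statistics, recovery regressions |
| `05_pulse_chase.R` | bleach calibration, corrected chase traces, turnover, rate fits |

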