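# cochleamod

Analysis of slow rhythmic modulation of **ongoing otoacoustic activity
(OOA)** — the sound the cochlea's active amplifier emits into the sealed ear
canal during silence — and of its modulation by intermodal attention.

The package is written for auditory neuroscientists who record ear-canal
microphone signals during silent cue–target intervals and want to answer
three questions:

1. Is the OOA envelope rhythmically modulated at low (theta-band)
   frequencies, beyond what a 1/f aperiodic spectrum explains?
2. Does the modulation strength differ between auditory and visual
   attention?
3. Do individual differences in that cochlear modulation covary with
   cortical oscillatory power?

## What it computes

Per subject and ear, recordings are epoched, screened for saturation,
high-pass filtered at 500 Hz (6th-order zero-phase Butterworth), decomposed
by a bank of 201 bandpass windows (1000–2000 Hz, ±30 Hz) into Hilbert
amplitude envelopes, and transformed into **induced** (power averaged over
trials) and **evoked** (trial-averaged envelope) modulation spectra over
1–30 Hz. Each spectrum is parameterized as

    log10 P(f) = b − χ·log10 f + Σ_k A_k · exp(−(f − CF_k)² / 2σ_k²)

— an aperiodic offset/exponent plus Gaussian peaks — and the primary
sub-11 Hz peak is validated with Dixon's Q against the non-peak power
distribution, aggregated by an exact binomial test. The **attention
modulation index**

    AMI = (Attend Auditory − Attend Visual) / (Attend Auditory + Attend Visual) × 100

is pooled over the theta range (3–10 Hz left ear, 1–10 Hz right ear) and
tested with FDR-corrected one-tailed one-sample t tests. Peak-frequency
uniformity (Kolmogorov–Smirnov), evoked-phase comparisons (common circular
median test), reaction-time median splits with repeated-measures ANOVAs,
and **cluster-based permutation tests** on voxel × frequency source-power
grids (condition contrast via sign flips; across-subject brain–cochlea
correlation via subject permutation; max-mass null, +1-corrected
Monte-Carlo p) complete the battery.

A seeded synthetic-data module (`simulate_subject()`,
`simulate_brain_power()`) generates ear-canal cohorts, behavioral tables,
and source grids with planted effects so the whole pipeline is testable
against known ground truth.

## Worked example

```r
library(cochleamod)

cfg  <- generator_config(n_subjects = 6, seed = 42)     # 40 trials/condition,
scfg <- study_config(cfg, n_windows = 51, n_perm = 500) # f_m = 6 Hz planted
man  <- run_study(scfg, out_dir = tempfile())
rep  <- man$report
```

The run simulates the cohort, executes the full signal path, and writes
config, trial tables, spectra, a tidy test table, a JSON report, and a
checksummed manifest into a fresh run directory. The report for this seed
prints:

```
Induced peak (right ear, attend auditory): 6.16 Hz (SD 0.42)
Aperiodic slope (right ear): 0.376
Pooled AMI right ear: 4.66% (SE 0.61), t = 7.62, p = 0.0003
Dixon Q significant peaks: 19 of 20 (binomial p = 4e-05)
Condition cluster: p = 0.044 (positive)
Brain-cochlea correlation cluster: p = 0.008 (negative)
```

Reading: the planted 6 Hz cochlear rhythm is recovered within the
across-subject jitter; the aperiodic exponent is in the expected range; the
pooled theta AMI is positive (auditory > visual) and significant; nearly
all primary peaks are significant spectral outliers; source space shows the
planted positive (auditory > visual) power cluster and the planted negative
correlation between cortical AMI and cochlear AMI.

## Package layout

- `R/synth.R` — seeded generators (ear trials, subjects, envelope process, brain grids)
- `R/preproc.R` — epoching, saturation rejection, filtering, bandpass bank, modulation spectra
- `R/specparam.R` — aperiodic/periodic spectral fits, Dixon's Q, exact binomial, evoked phase
- `R/stats.R` — AMI, pooling, t tests, FDR, KS uniformity, circular median test, RM-ANOVA, median splits
- `R/cluster.R` — spatio-spectral adjacency and permutation cluster tests (Rcpp kernel in `src/`)
- `R/workflow.R` — per-subject pipeline, group statistics, `run_study()`, reports, manifests
- `vignettes/cochlear-modulation-methods.Rmd` — model assumptions, parameter choices, limitations
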