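---
title: "Methods: quantifying attentional modulation of ongoing otoacoustic activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying attentional modulation of ongoing otoacoustic activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

The healthy cochlea is not a passive microphone: its outer hair cells
actively amplify incoming sound, and that amplifier leaks energy back into
the sealed ear canal as measurable sound — otoacoustic activity. During
silent periods this *ongoing* otoacoustic activity (OOA) carries no stimulus
response at all, which makes it a rare window onto purely top-down
(efferent, medial olivocochlear) influences on the auditory periphery. The
scientific question this package operationalizes is whether the slow
(theta-band, roughly 3–8 Hz) amplitude modulation of OOA changes when a
listener attends to sound versus to a visual target, and whether
individual differences in that cochlear modulation covary with cortical
oscillatory power.

`cochleamod` implements the complete analysis path from raw two-ear
microphone recordings to group inference, together with a seeded synthetic
cohort generator so that every stage is testable against planted ground
truth without access to raw study data.

## Signal path

Per subject and ear the pipeline is:

1. **Epoching.** 3 s epochs are cut from the continuous ear-canal
   recording, starting at the onset of the silent cue–target interval
   (which follows a 1 s attention cue). Trials whose epoch would leave the
   recording are dropped individually with a reason code.
2. **Saturation rejection.** Microphone overload produces runs of samples
   pinned at full scale. A trial is rejected when it contains at least
   2 ms of consecutive samples with |x| ≥ 0.999 × full scale. This is an
   automated replacement for manual screening, and it must run on the *raw*
   epochs: a 500 Hz zero-phase high-pass turns a clipped plateau into a
   near-zero stretch with edge ringing, hiding exactly the evidence the
   detector needs. The package therefore orders the stages
   epoch → reject → filter; because the subsequent filters are zero-phase
   and linear, retained-trial content in the passband is identical to the
   filter-first ordering.
3. **High-pass filtering.** 6th-order Butterworth at 500 Hz, applied
   forward–backward (zero phase, squared magnitude response). In the
   per-subject pipeline the response is applied in the frequency domain
   fused with the filter bank (the bank is linear and diagonal in
   frequency, so this is exact); the standalone `highpass_oae()` uses
   `signal::filtfilt` on time series.
4. **Bandpass bank with Hilbert envelopes.** 201 bands centered at
   1000–2000 Hz in 5 Hz steps, each ±30 Hz wide. Each band's amplitude
   envelope is the magnitude of its analytic signal. Implementation: the
   epoch's FFT is sliced per band (a brick-wall zero-phase selection), and
   the slice is inverse-transformed at a demodulated rate of 100 Hz. The
   analytic-signal magnitude is invariant to the frequency shift, so this
   yields the Hilbert envelope of the bandpassed signal directly at a rate
   that comfortably covers the 1–30 Hz modulation range while keeping the
   201 × trials × samples array desk-sized. The band count and spacing
   follow the explicit window count (201 over a 1000 Hz span forces 5 Hz
   steps); both are configuration knobs.
5. **Modulation spectra.** Envelopes are analyzed within 0.25–1.95 s of
   the epoch — the central 1.7 s of the cue–target interval, avoiding cue
   offset and target anticipation edges. Each windowed envelope is
   demeaned (otherwise the envelope's DC level dominates the lowest bins
   through leakage), Hann-tapered, and Fourier transformed with zero
   padding to a 0.25 Hz grid (native resolution 1/1.7 s ≈ 0.59 Hz).
   *Induced* spectra average power across trials and therefore retain
   rhythms with trial-varying phase; *evoked* spectra average the
   envelopes first and retain only phase-locked modulation, with complex
   coefficients kept so the evoked phase is defined. The one-sided
   densities satisfy Parseval within 1% (taper-gain corrected), which the
   test suite checks.

## Spectral parameterization

Band-averaged modulation spectra are decomposed into an aperiodic
component and Gaussian peaks:

log10 P(f) = b − χ·log10 f + Σₖ Aₖ·exp(−(f − CFₖ)² / 2σₖ²)

The fit is the standard iterative scheme: a robust log–log line fit that
ignores points protruding above the trend, residual-maximum peak seeding
with half-height bandwidth guesses, a joint bounded least-squares refit of
all Gaussians (CF within the fit range, σ ∈ [0.25, 6] Hz to exclude spike
and plateau degeneracies), and a final aperiodic refit on the peak-removed
spectrum. A fixed (no-knee) aperiodic form is used because a single slope
per spectrum is the quantity of interest. On noiseless synthetic spectra
the fit is exact to ±0.001; on stochastic 40-trial spectra of the
generator's envelope process the exponent is recovered within ±0.2 for
χ ∈ {0.3, 0.8, 1.5}.

When several peaks sit below the 11 Hz limit, the *primary* peak is the
one with the largest amplitude (an explicit, configurable rule; taking the
lowest center frequency is the exposed alternative). A spectrum with no
sub-11 Hz peak is flagged, never silently dropped.

**Peak significance.** Whether the power at the primary peak is an outlier
of the non-peak power distribution is tested with Dixon's Q (gap to the
nearest neighbor over the sample range, two-sided critical values at
α = 0.05 embedded for n = 3…30). Two choices had to be made explicit:
the comparison is performed on the aperiodic-flattened log power (on raw
1/f spectra the lowest bins would always dominate the range and the test
would be blind), and the non-peak bins are subsampled to a ~1 Hz grid,
excluding bins within 1.5 bandwidths of any fitted peak, so the pooled
sample size stays inside Dixon's 3–30 applicability window.
Inapplicability is a reported status, mirroring how spectra that fail the
test's requirements are excluded rather than counted. The per-spectrum
outcomes aggregate into an exact binomial test of the success proportion
against 0.5, computed by the minimum-likelihood two-sided rule.

## Group statistics

The attention modulation index per spectral cell is
AMI = (Auditory − Visual) / (Auditory + Visual) × 100, a contrast bounded
in ±100%. Pooling over the theta range (3–10 Hz left ear, 1–10 Hz right
ear, over the full 1000–2000 Hz carrier range) averages the *index*, not
the power: the index is the quantity being summarized, and averaging it
keeps each cell's contribution bounded; pooling power first is the exposed
alternative and agrees in sign. Group inference uses one-tailed
one-sample t tests against zero (direction fixed a priori: auditory >
visual), Benjamini–Hochberg correction across ears, and a two-sided paired
t for the interaural comparison.

Peak-frequency distributions are tested against uniformity with a
one-sample Kolmogorov–Smirnov test; both the classical D ∈ [0, 1] and
√n·D are reported because conventions differ between packages (published
values above 1 are √n-scaled), with the asymptotic p either way. The
support interval defaults to 1–11 Hz (the peak search window) and is
configurable. Evoked phases are compared between ears and between
modalities with a common-circular-median test: the pooled circular median
defines a semicircle, per-group membership counts form a χ²(1)
proportion-homogeneity statistic. Membership (angular distance from the
median below π/2) rather than side-of-diameter is used because a group
shifted toward the antipode straddles the median's own diameter
symmetrically and would be invisible to the side count, while any median
shift changes semicircle membership; under a common median both rules are
calibrated.

Reaction-time sensitivity is assessed by splitting trials at the median RT
*separately per subject and condition* (a pooled split would confound the
condition shift with speed), with ties assigned to the fast group so the
halves differ by at most one trial. The 2×2×2 (ear × RT × condition) and
2×2 repeated-measures ANOVAs report main effects only; for two-level
within factors the classical main-effect F equals the squared paired t on
subject-level means collapsed over the other factors, with df (1, n − 1),
which is how it is computed.

## Cluster-based permutation inference

Source-space power maps (voxel lattice × 1 Hz frequency bins, restricted
to 3–25 Hz) are tested nonparametrically. Cell statistics are paired t
values (condition contrast) or t-transformed Pearson correlations with the
per-subject cochlear AMI (brain–cochlea association). Cells exceeding the
two-sided parametric threshold at α = 0.05 are clustered: voxels are
spatial neighbors within one lattice step in each coordinate, cells
connect spatially at the same frequency or across adjacent frequency bins
at the same voxel, with no diagonal space–frequency edges. Cluster mass is
the sum of the cell statistic, and the null distribution of the maximal
|mass| comes from per-subject sign flips of condition differences or from
permuting the subject order of the cochlear vector (which preserves the
brain maps' spatial covariance). Monte-Carlo p-values use the +1
correction; exhaustive enumeration (all 2ⁿ sign patterns, all n!
orderings) replaces sampling for small n and is cross-checked against the
Monte-Carlo path in the tests. Family-wise error measured over 500 null
replicates on a 6×6×6 grid falls in the 2–9% band around the nominal 5%.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions the acceptance properties run under:

* **Carrier.** White noise bandpassed to 1000–2000 Hz with a 4th-order
  zero-phase Butterworth response, regenerated per trial so no evoked
  structure can arise from the carrier itself. OOA is broadband and
  noise-like; no biophysical (transmission-line or hair-cell) model is
  attempted.
* **Envelope.** e(t) = max(0.05, 1 + d·sin(2π f_m t + φ) + a(t)), with
  condition-dependent depth (defaults d_A = 0.25, d_V = 0.15), f_m = 6 Hz
  jittered across subjects (SD 0.5 Hz) to emulate the reported
  interindividual spread, and per-trial uniform phase (or a fixed phase in
  locked mode, which models a phase-aligned, evoked rhythm). a(t) is
  spectrally shaped noise with amplitude ∝ f^(−χ/2) below 30 Hz (χ = 0.4
  by default, matching slopes typical of measured modulation spectra), and
  the 0.05 floor keeps the envelope positive at extreme draws without
  rejecting configurations.
* **Noise and artifacts.** Additive white measurement noise (SD 0.1 of
  carrier RMS); 5% of trials receive a 50 ms run clipped exactly at ±full
  scale, which the saturation detector must catch.
* **Behavior.** Lognormal reaction times (median ≈ 450 ms, σ = 0.25 in log
  space) with a +60 ms shift for auditory trials, and Bernoulli accuracy at
  93% — a ceiling, which is why the analysis battery treats RT, not
  accuracy, as the performance variable.
* **Brain grids.** 8×8×8 voxels at 1 cm, lognormal power around a 1/f
  profile. A posterior corner block carries a multiplicative
  auditory > visual effect at 8–25 Hz; a temporal corner block's condition
  effect is scaled per subject as ρ·z + √(1−ρ²)·η against the standardized
  cochlear AMI vector, planting a correlation of ρ (−0.8 by default).

**What the generator does not emulate.** Real OOA levels (the generator is
in arbitrary units; absolute dB SPL calibration is out of scope), spectral
tilts of the carrier within 1000–2000 Hz, non-stationary attention drifts
within the interval, ear asymmetries, and any sensor-level MEG physics —
the grid stands in for already source-projected power. Passing tests
therefore demonstrate that the *analysis* recovers planted structure of
the assumed form at realistic sizes and noise levels, not that real ears
behave like the generator.

**A physical limit worth knowing.** The envelope of any 60 Hz-wide slice
of a noise carrier fluctuates intrinsically (for Gaussian noise the
envelope's relative variance is 4/π − 1 ≈ 0.27, spread over 0–60 Hz).
This adds a floor of roughly 0.005/Hz (relative) to every measured
modulation spectrum, independent of trial count. The planted 1/f^χ
envelope component therefore dominates only at low modulation frequencies,
and the slope fitted to full-pipeline spectra (≈ 0.37 under defaults) is a
floor-attenuated version of the generative χ = 0.4. For this reason the
exponent-recovery property is stated on the generator's envelope process
observed directly (`simulate_envelope_trials()`), where the spectral
content is exactly known — that is the input the parameterizer is
responsible for, and the floor is physics, not an estimator defect.

## Numerical choices and problem sizes

* All filtering is zero-phase; evoked phase extraction compensates the
  Fourier phase to the analysis-window center (where a symmetric taper
  makes the phase estimate robust to bin mismatch) and rewinds it to the
  epoch origin at the requested frequency, returning the modulator's sine
  phase convention.
* Determinism: a cohort is a pure function of its configuration and seed;
  per-subject and per-stage RNG streams are derived from the study seed.
  Fixed seeds reproduce cluster results bit-for-bit.
* The test suite keeps replicate sweeps desk-sized: AMI-direction cohorts
  use the right ear and 21 bandpass windows (the pooled index is
  insensitive to band density), global-null end-to-end runs use 8 subjects
  and 200 permutations, and the null-calibration suite uses a 6×6×6 grid
  with 500 replicates of 500 permutations. Generator effect parameters
  (trial counts, depths, rates, frequencies) are never reduced.
* Degenerate inputs are statuses, not crashes: zero-variance t tests,
  inapplicable Dixon's Q, all-identical reaction times, empty cluster
  results, and missing report stages all carry explicit flags.

## Known limitations

* The aperiodic fit is fixed-mode; spectra with a genuine knee would bias
  the exponent (knee-mode fitting is a stated non-goal).
* Dixon's Q requires the 1 Hz non-peak subsampling described above; with
  denser grids the test is reported inapplicable by design.
* The cluster-forming threshold is parametric and configurable; no TFCE
  variant is provided.
* The correlation cluster test sums t-transformed correlations; summing r
  directly would weight cells differently (the t-sum convention is fixed
  here).
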