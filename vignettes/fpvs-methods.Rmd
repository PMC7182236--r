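---
title: "Frequency-tagged analysis of expression regularities: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-tagged analysis of expression regularities: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The paradigm

In a fast periodic visual stimulation (FPVS) oddball design, face images
stream at a fixed stimulation rate (15 Hz or 6 Hz here) while a designated
facial expression recurs on every third image. A visual system that
extracts the recurring category produces a steady-state response at the
regularity rate — the stimulation rate divided by three (5 Hz or 2 Hz) —
distinguishable in the EEG spectrum from the response at the stimulation
rate itself. Because the regularity response is weak, the analysis asks a
sharper question than "is there spectral power": *is the response phase
consistent across trials?* The pipeline in this package goes from stimulus
scheduling to a Bayesian comparison of phase-clustering values across
conditions, with a forward simulator standing in for recordings.

## Stimulus scheduling (`experiment_spec`, `build_sequence`, `schedule_targets`)

Four presets reproduce the study designs this pipeline targets:

| preset | stream | regularity | trial | cells × trials | min target gap |
|--------|-------|-----------|-------|----------------|----------------|
| pilot1 | 15 Hz | 5 Hz | 3.8 s | 6 × 96 | 600 ms |
| pilot2 | 15 Hz | 5 Hz | 3.8 s | 12 × 48 | 600 ms |
| exp1   | 6 Hz  | 2 Hz | 7 s   | 12 × 48 | 800 ms |
| exp2   | 6 Hz  | 2 Hz | 7 s   | 12 × 30 | none (passive) |

Sequences are built triplet-wise. In regular conditions the first cycle of
every triplet carries the regular expression (angry or neutral); the two
filler positions draw from the remaining categories under a per-trial
balance quota, so filler expressions are evenly distributed within each
sequence (a session-level audit follows for free, since every trial is
balanced). Happy and disgusted images are filler-only: they never occupy a
triplet-first position, in any condition. Irregular triplets contain three
distinct categories in random order; with four categories available, the
omitted category rotates under its own balance quota, and the first
position is restricted to the regular-capable categories so that the
filler-only rule holds uniformly. Where several identities are in play
(the 9-identity design), no identity-plus-expression token of one triplet
may reappear in the following triplet; with one identity per trial the
token constraint is vacuous for the regular expression by design and is
therefore not applied.

Trial counts follow the printed designs: 576 trials (96 per condition) for
the 15 Hz detection designs and 360 for the passive design. The passive
design's "60 trials per condition" counts orientation-by-regularity
conditions; identity variability splits each into two cells of 30. Target
scheduling marks 36 of 96 trials per condition (37.5%, the count that
leaves 60 analysable trials per condition after discarding responses; the
printed "40%" is approximate), draws 1–3 target onsets per target trial
uniformly over the frame grid, and enforces the minimum onset-to-onset
interval exactly: the interval quantizes to whole frames (36 frames at
60 fps = 600.0 ms), so the scheduler's minimum gap equals the nominal one.
Sampling uses the classic spacing construction (sample without replacement
from a shrunken grid, then re-expand), which is exactly uniform over valid
placements rather than rejection-based.

## The forward simulator (`forward_model`, `simulation_config`, `simulate_experiment`)

The simulator emulates the features of scalp EEG this analysis is
sensitive to, not cortical physiology:

* a 64-channel scalp montage plus 4 EOG channels at 256 Hz. Electrode
  positions are a synthetic Fibonacci lattice on a spherical cap with `Cz`
  at the vertex; only inter-electrode angles matter (spline interpolation,
  topography displays), so no digitised cap is shipped;
* a stimulation-rate sinusoid on a parieto-occipital topography, tightly
  stimulus-locked (von Mises trial phase, concentration 50);
* a regularity-rate sinusoid, regular conditions only, on a slightly
  offset topography; its trial phase is von Mises with per-condition
  concentration kappa — the quantity the whole analysis chain is meant to
  recover;
* spatially correlated `1/f` noise (generated in the frequency domain for
  exact spectral control, then mixed by the Cholesky factor of a
  distance-decay channel correlation), a 10 Hz alpha rhythm, and optional
  400 ms raised-cosine blinks on the EOG channels with 10% scalp leakage.

Default amplitudes are 20 µV (stimulation source) and 10 µV (regularity
source) against 10 µV RMS broadband noise: at the sensor level this puts
the peak-channel responses at roughly 5 µV and 2.5 µV, giving the clearly
visible spectral peaks the analysis presumes, while single-trial phase
still carries measurement noise. Per-condition effects are planted on the
CS scale and converted to kappa through the analytic bridge
`E[CS] = (I1(kappa)/I0(kappa))^2` (`expected_cs`, `kappa_for_cs`); the
default preset mirrors the magnitudes typical of the paradigm (neutral
0.05 above angry 0.03, scaled 1.25×/0.75× for high/low identity
variability, irregular 0), but these are presets, not calibration targets.

What the simulator does *not* emulate — and what passing tests therefore
cannot certify about real recordings: volume-conducted source mixtures
beyond three fixed topographies, non-stationary noise, muscle and saccade
artifacts, harmonic structure of the steady-state responses, and realistic
broadband-to-signal power ratios (real SSVEPs are far smaller relative to
background than the defaults here; consequently, condition-blind epoch
screening on simulated mixed designs can show mildly elevated rejection in
the conditions with less signal power, which disappears on power-matched
conditions).

## Artifact screening (`preprocess`, `screen_channels`, `screen_epochs`)

The cascade mirrors a FASTER-style pipeline: average reference; screening
of whole channels over the recording (variance, mean correlation, Hurst
exponent by detrended fluctuation analysis over dyadic windows of 16–256
samples, each z-scored across channels at ±3) followed by
spherical-spline interpolation (order 4, stiffness 1e-5); re-reference to
`Cz`; epoch-level rejection on channel-mean amplitude range, variance and
deviation; within-epoch channel repair; per-condition rejection including
the maximum EOG amplitude; discarding of epochs with more than 12
repaired channels; kurtosis and spectral-deviation screens (±50 dB at
0–2 Hz, +25/−100 dB at 20–40 Hz against the median log-spectrum
baseline); and a final average reference over scalp electrodes only.

Three numerical choices deserve explanation:

* **Correlation screens low agreement only.** A channel that duplicates
  its neighbour has high mean correlation; high agreement is not an
  artifact, so only the low side of the correlation z is flagged.
  Variance and Hurst remain two-sided.
* **The within-epoch channel screen is two-stage.** A mean/sd z over 64
  channels can mathematically never flag more than ~7 of them (Chebyshev),
  which would make the 12-channel discard rule unreachable, while a pure
  median/MAD z misreads the structured cross-channel distribution of
  variance-type metrics. The screen therefore first isolates gross
  corruption with a median/MAD z at a high cutoff (8), then applies the
  ordinary ±3 z with mean and sd taken over the non-gross channels.
  Scale metrics enter on the log scale (symmetric across channels), the
  deviation metric signed. Metrics are computed on an average-referenced
  copy of the epoch, because a point reference like `Cz` imprints a steep
  distance gradient on every scale metric; the repair itself happens in
  the data's own reference frame.
* **Kurtosis is a conjunction.** An epoch is discarded when a channel's
  kurtosis deviates more than 5 SD from *both* its own channel's mean and
  the all-channel mean; the one-sided `eog_max` criterion flags only
  abnormally large ocular amplitude.

Rejection reports carry one reason code per firing screen
(`amplitude_range`, `variance`, `channel_deviation`, `eog_max`,
`kurtosis`, `spectral_deviation`, `over_interpolated`) and per-condition
percentages. On artifact-free, power-matched simulations the cascade's
false-positive budget stays within 5% per condition.

## Spectral analysis (`truncate_detrend`, `ress_fit`, `spectrum_fft`, `phase_at`)

Epochs are truncated to the analysis window — 3 s starting 0.5 s after
RSVP onset for the 15 Hz designs, 6.5 s for the 6 Hz designs — and
linearly detrended. Per condition, a spatial filter is derived by
generalized eigendecomposition (RESS): the signal covariance `S` is the
mean per-trial covariance of data Gaussian-filtered at the target
frequency (FWHM 1 Hz, i.e. a ±0.5 Hz band), the noise covariance `R`
averages the two flanking bands at ±1 Hz (FWHM 0.5 Hz), pooled before
regularization by 1% of its mean eigenvalue on the diagonal. The leading
generalized eigenvector (solved by whitening with the regularized `R`,
then a symmetric eigenproblem) is the filter; its sign is fixed by making
the largest-magnitude weight positive, and the displayed topography is
the unit-norm back-projection `S w`. Per-trial covariances are averaged
rather than computed on concatenated data, for robustness to trial-count
imbalance; average-referenced data loses one rank by construction, so the
rank-deficiency warning fires only beyond that one null direction.

Filter-projected single trials are Tukey-tapered (taper fraction 0.25 by
default; the fraction is exposed because no canonical value exists),
zero-padded to 10 s and Fourier-transformed, which puts every experiment
on an exact 0.1 Hz grid; 5 Hz and 2 Hz land on-grid by construction, and
`phase_at` refuses off-grid frequencies rather than snapping silently.

## Phase clustering (`cs_index`, `cs_index_closed`, `itc`)

The cosine similarity index is the mean cosine of the phase difference
over all trial pairs:

CS = 2 / (n (n − 1)) · Σ_{i<j} cos(θ_i − θ_j).

Its expectation is 0 under uniform phases at any trial count — unlike ITC
(`R/n`), whose small-sample bias is about `sqrt(pi / (4 n))` (0.198 at
n = 20). The production implementation is the O(n) closed form
`(R² − n) / (n (n − 1))` with `R` the resultant length; the explicit
pairwise sum is retained as its oracle, and the two agree to 1e−12 on
random phase sets. Under independent von Mises phases CS estimates
`(I1(kappa)/I0(kappa))²` without bias, which is what lets the simulator
plant effects on the CS scale. Significance against "no phase locking" is
assessed by a per-trial uniform phase-rotation null (`cs_null`):
equivalent to the uniform null for any phase-only statistic while keeping
per-trial spectra intact. Per-condition filters can overfit noise when no
regularity source exists; empirically this biases irregular-condition CS
slightly *negative* (pairwise phase differences pushed apart), which is
why irregular-vs-irregular contrasts are marked uninterpretable
downstream.

## Inference (`fit_cs_model`, `contrast`, `classify_er`)

CS values (one per participant and condition cell) enter a Gaussian
multilevel model with cell-means coding — every reported quantity is a
pairwise cell difference, which cell means deliver directly — and
participant-varying intercepts only. Priors: Normal(0, 3) on cell means,
half-Student-t(3, 0, 2) on the participant and residual SDs (the residual
SD is not named in the source analysis; the same weakly-informative scale
prior is used). Sampling runs 8 chains × 8,000 iterations with 4,000
warmup and thinning 2 — 16,000 retained draws per parameter — via
Gibbs/slice MCMC (JAGS), which satisfies the plan's diagnostics; R-hat
(threshold 1.05), effective-sample ratio (0.1) and Monte Carlo standard
errors are computed per parameter and a failing fit is flagged with a
warning, never returned silently.

Contrasts summarise difference draws by their mean, the narrowest-window
95% HDI, and the evidence ratio — the ratio of posterior draws on the
hypothesised side of zero. Bands: below 3 inconclusive, 3–10 anecdotal,
10 and above strong, `Inf` (all draws on one side) very strong; boundary
values go to the higher band since the source thresholds are open
intervals. A zero denominator yields `Inf`, a zero numerator 0. The
direction defaults to the side of the posterior mean but should be fixed
a priori when calibration matters: under the null, the winning-side ratio
reaches "strong" about twice as often as a pre-stated direction does.

## Problem sizes used in the checks

The test suite favours scales that isolate each property: the estimator
bridge is verified in two parts, because a single 500-epoch CS estimate
has phase-sampling sd comparable to the ±0.03 band — the
filter/spectrum/phase chain must reproduce the CS of 500 epochs with
*known* planted phases to ±0.01 (measurement), and the CS of 500
replicate von Mises phase sets must average to the Bessel-ratio
expectation to ±0.03 for each concentration (sampling); the end-to-end
replication simulates six participants with 60 trials in each of three
upright conditions — the per-condition trial count the detection designs
retain after discarding target trials — through the full screening
cascade, comparing each condition's across-participant mean CS against
the 95th percentile of the matching phase-rotation null; hierarchical
recovery plants a 0.03 cell difference (residual SD 0.02, participant SD
0.01, 16 participants) and averages the posterior-mean error over four
replicate datasets under a reduced 4 × 2,000 sampler, because a single
dataset's sampling error (≈0.007) is of the same order as the ±0.01
check. The full 8 × 8,000 plan is exercised separately for its
diagnostics. Null calibration (fewer than 10% of directional contrasts
reaching "strong" on null data) sits deliberately close to its
theoretical value of ≈9%; it is run at 100 replicates.

## Known limitations

* The synthetic montage is geometric, not a digitised cap; spline
  interpolation accuracy on real caps will differ in detail.
* Epoch serialization uses Parquet (long format) rather than a
  neuroimaging container; BDF/EDF ingestion is out of scope.
* The spectral-deviation baseline is the median log-spectrum across a
  subject's epochs, one defensible choice among several.
* No harmonic summing: the analysis targets the fundamental regularity
  frequency only.
* Evidence-ratio calibration under the null is inherently marginal with
  respect to the "strong" band; treat bands as descriptive labels, not
  error-rate guarantees.
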