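---
title: "Modelling and analysing temporal-prediction EEG with tpeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing temporal-prediction EEG with tpeeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpeeg)
```

## The task and its observables

`tpeeg` analyses an occluded-motion temporal prediction task. A stimulus
moves visibly for 1000–1500 ms, disappears behind an occluder, and reappears
after a nominal 1500 ms interval shifted by a signed offset
$\Delta t \in \{\pm 34, \pm 134, \dots, \pm 934\}$ ms; the reappeared
stimulus stays visible for 500 ms and the participant judges the
reappearance as *too early* or *too late*. A session is eight blocks of 60
trials (480 trials), and epochs are cut 1240 ms before movement onset to
1240 ms after stimulus offset, so epoch lengths range from 4546 ms to
6914 ms.

Two families of observables matter:

* **Behavior.** The proportion of *too late* responses as a function of
  $\Delta t$ is summarized by a binomial logistic psychometric function. The
  *point of subjective equality* (PSE) is the offset with a 50% *too late*
  rate, $-b_0/b_1$; the *steepness* is the reciprocal of the offset span
  between the 25% and 75% points, which for the logistic equals
  $b_1 / (2\ln 3)$.
* **Oscillations.** Beta-band (13–30 Hz) power is suppressed relative to a
  pre-movement baseline (−500 to −200 ms) throughout the prediction
  interval, and delta-band (0.5–4 Hz) phase aligns to the disappearance of
  the stimulus, measured as inter-trial phase consistency (ITPC).

## The synthetic cohort generator

No public recordings exist for this paradigm, so every stage is driven by a
simulator with recoverable ground truth:

* **Behavioral observers** respond *too late* with probability
  $\lambda/2 + (1-\lambda)\,\mathrm{logit}^{-1}\{2\ln 3\, s\,(\Delta t -
  \mathrm{PSE})\}$. Parameterizing by $(\mathrm{PSE}, s)$ keeps the ground
  truth on the same steepness scale the analysis estimates, so recovery is a
  direct comparison. The fitted model has no lapse term (a plain binomial
  GLM, as the analysis standard for this task prescribes); the simulator's
  lapse defaults to 0 so generator and fit are conjugate, and sensitivity to
  a nonzero lapse is a test, not a model term. Reaction times are a
  truncated normal placeholder — they are descriptive in this design, not an
  inference target.
* **Background EEG** is per-channel Gaussian noise spectrally shaped to
  $1/f^{a}$ (default $a = 1$), 10 µV RMS.
* **The beta generator** is narrow-band noise centered at 21 Hz whose
  envelope drops by a configurable fractional power change (default −0.4)
  from movement onset to reappearance, with 100 ms ramps.
* **The delta generator** is a constant-amplitude 2 Hz oscillation whose
  free-running phase is replaced, at each stimulus disappearance, by a von
  Mises draw with concentration $\kappa$. This phase-reset mechanism
  produces ITPC without any power change, so power and phase effects can be
  manipulated independently.
* Both generators are focal dipoles projected to the sensors through the
  package's spherical forward model; `snr` sets the generator-to-background
  RMS ratio, and `snr = 0` leaves pure background.
* Movement intervals are drawn continuous-uniform (the task description
  specifies only a varying starting position), rounded to the 1 ms sampling
  grid; the inter-trial interval is the 1500 ms fixation with no extra
  jitter.
* An optional comb of sinusoids at a stimulation frequency and its
  harmonics can be enabled to exercise the low-pass/band-stop stages; no
  stimulator artifact is simulated by default.

What the simulator does **not** emulate: ocular/muscle/cardiac artifacts
(removed by manual ICA in real pipelines, out of scope here), head movement,
realistic cortical geometry, or volume-conduction inhomogeneities. Passing
tests therefore demonstrate correctness of the analysis machinery under
known ground truth, not robustness to every property of patient data.

## Spectral analysis

The Morlet bank uses 40 wavelets log-spaced 0.5–100 Hz with cycles log-spaced
2–10 in step with frequency ($\sigma_t = c/2\pi f$). Kernels are unit-energy
(so power is comparable across frequencies; a unit-amplitude option exists)
and mean-corrected so a constant signal produces exactly zero response —
without the correction the 2-cycle wavelets pass appreciable DC. The
convolution is FFT-based, linear, and center-aligned.

Coefficients are retained on a decimated grid (default one sample per
20 ms), which keeps a session's complex TFR in memory; power and ITPC are
computed per retained sample and then averaged within 100 ms bins. Averaging
ITPC values within bins (rather than pooling phases across a bin) is the
conservative reading of binning ambiguity; pooling is available via finer
decimation.

Edge handling: a 0.5 Hz wavelet at 2 cycles spans several seconds, longer
than the 1240 ms pads, so early/late low-frequency bins are *masked* (kept,
flagged invalid, excluded from statistics) rather than NaN-poisoned.
Baseline normalization defaults to relative change at sensor level and
z-scores for source summaries, matching how such maps are usually displayed;
the mode is always recorded in the output.

## Cluster-based permutation statistics

Maps of channels (or voxels) × frequencies × 100 ms bins are tested across
participants with cluster-based permutation inference: the observed
statistic map is thresholded at the two-sided parametric quantile of the
cluster-forming alpha (default 0.05), same-sign suprathreshold neighbors are
joined into clusters (channel adjacency from great-circle distance with
median degree ≈ 6; voxel adjacency 26-connectivity; frequency and time
chains toggleable), and each observed cluster's |mass| is compared with the
permutation null of the **maximum |mass| over both signs**. The max-statistic
construction is what makes the family-wise error rate provably at most the
nominal level; the per-tail nulls are stored as well. Permutation schemes:
sign flips for one-sample/paired designs (exhaustive with a warning when
$2^n$ does not exceed the requested count), group-label reshuffles for
independent groups, and score permutation for correlation maps. The +1
correction keeps p-values strictly positive, and permutation seeds are
stored for replay.

Mass (not size) is the cluster statistic and tests are two-sided throughout;
both choices are recorded here because the convention is often left
unstated.

## Source analysis

The forward model is a homogeneous conducting sphere (85 mm radius, 0.33
S/m) with an analytic closed-form surface potential, derived by summing the
Legendre expansion of the interior dipole field with generating functions.
The closed form is validated in the tests against an independent truncated
series to $10^{-10}$. This replaces MRI-based realistic head modelling — a
documented approximation; externally computed leadfields can be supplied.

DICS beamforming follows standard practice: cross-spectral density matrices
from the wavelet coefficients in 100 ms steps, averaged over the analysis
band and window; filters $W = (L^T C_r^{-1} L)^{-1} L^T C_r^{-1}$ from the
real part of the regularized common CSD
($\lambda$ = `lambda_frac` × mean sensor power, default 5%); scalar filters
along the dominant orientation of the 3×3 source CSD. Scalar filters are
mandatory for source ITPC (the phase of a 3-vector is ill-defined). One
filter set computed from condition-pooled data is applied to every condition
entering a contrast, so condition differences are not confounded by filter
differences; pooling is over exactly the units entering each contrast.

Numerical behaviors worth knowing:

* Raw minimum-variance power is depth-biased; localization uses the neural
  activity index (`normalize = "nai"`, power over projected white-noise
  power).
* An adaptive filter evaluated *near* but not *at* a focal source partially
  suppresses that source (classic mislocation suppression). At the default
  5% regularization the point spread of a strong focal effect can shrink to
  roughly one voxel, which starves cluster statistics — a cluster of one
  voxel carries almost no mass while smooth chance patterns in the
  permutation null carry a lot. Group-level ITPC–behavior correlation maps
  therefore use heavily regularized filters (`lambda_frac = 5`), trading
  spatial sharpness for a point spread wide enough that true effects form
  spatially extended clusters. This is a deliberate design choice of the
  package, documented because the default would silently lose power.
* The unit-gain identity $W L = I_3$ holds to machine precision at
  $\lambda = 0$ and is asserted in the tests.

## The pipeline

`run_pipeline()` chains simulate → (optional) filter → epoch → behavioral
fit → subjectively-correct trial selection → Morlet decomposition →
baseline-normalized beta power and delta ITPC maps → group cluster contrasts
(patients OFF vs ON paired; OFF and ON vs controls independent) → optional
source stage and ITPC–steepness correlation. All randomness flows from one
root seed through named substreams, so two runs with the same configuration
are bit-identical; per-test permutation seeds, the config hash and package
version are carried in the result. Filtering is zero-phase
(forward–backward order-4 Butterworth: 0.5 Hz high-pass, 95 Hz low-pass,
49.5–50.5 Hz band-stop). ICA is represented by a no-op stage boundary: the
synthetic data carry no artifacts, and the slot exists so a real workflow
can plug a component-removal step in. Variable-length epochs stay ragged;
rectangularization happens only at event-aligned binning.

Trials with missing or out-of-range markers are dropped with a log entry and
counted (`n_epochs + n_dropped = n_scheduled`); no other automated trial
rejection is applied, since visual artifact rejection has no automatable
criterion.

## Problem sizes used by the test-suite

The packaged checks run at desk scale by design: reduced montages (8–32 of
the 64 standard channels, chosen by farthest-point sampling so coverage
stays balanced), 200–250 Hz sampling, sessions of 30–60 trials, wavelet
banks restricted to the band under study, and source grids of 20–35 mm
spacing (the full 5003-voxel grid is exercised once through the
`target_count` solver). Statistical calibration uses 200 null cohorts of 12
subjects with 500 randomizations; psychometric recovery uses 500 simulated
observers at the full 480-trial session; beamformer localization uses 100
single-dipole replicates at sensor-level SNR 1; the coupled-cohort
correlation check uses 15 replicate cohorts of 13 subjects with the delta
generator placed on a grid node. These sizes are the package's choices for
fast, reproducible verification; every stage accepts full-scale inputs.

## Known limitations

* The spherical forward model ignores skull/scalp conductivity layering;
  absolute source amplitudes are not interpretable, only contrasts and
  locations.
* EDF output pads the trailing partial record with zeros (whole-second
  records); markers round-trip through the tab-separated events sidecar for
  both formats.
* The Firth-type fallback for separated psychometric data returns finite
  estimates but is flagged non-converged; ideal (noise-free) observers are
  the only way to reach it in practice.
* Degrees of freedom for independent-groups comparisons are reported both
  Welch (default) and pooled, because the two conventions differ and both
  appear in the literature; the multiple-comparison alpha defaults to
  0.05/3 for the three primary contrasts and is configurable.
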