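---
title: "Heart-rate-informed GLM analysis of block-design stress fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-rate-informed GLM analysis of block-design stress fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresswave)
```

## The analysis model

Classical analyses of block-design psychosocial stress tasks contrast a
Stress phase against control phases with uniform boxcar regressors, which
treats every stress block identically even though the cardiovascular
stress response differs strongly between individuals and fluctuates from
block to block. `stresswave` implements the complementary strategy of
*weighting* the task regressor by each participant's own heart rate: the
mean heart rate per active block, extracted from finger
photoplethysmography (PPG), enters the first-level GLM as a parametric
modulator of a single task regressor spanning all active blocks. Voxels
whose BOLD signal rises and falls with the participant's cardiovascular
arousal — beyond the mean task response — load on the modulator, in either
direction.

For scan $s$ and voxel $v$ the first-level model is

$$ y_v(s) = \beta_0 + \beta_{task}\, x(s) + \beta_{HR}\, m(s) +
  \gamma^\top n(s) + \varepsilon_v(s), $$

where $x$ is the HRF-convolved boxcar over all active blocks, $m$ is the
same boxcar with per-block heights equal to the *mean-centered* block
heart rate, convolved with the same HRF, and $n$ collects nuisance terms
(CompCor components, discrete-cosine drift, constant). The per-subject
$\hat\beta_{HR}$ maps are forwarded to a random-effects one-sample t-test
in the $+1$ and $-1$ directions.

The package ships five model variants behind one switch
(`run_config(variant = ...)`):

* `blockwise_hr` — the main model above;
* `volumewise_hr` — the modulator carries scan-wise heart rate (centered
  over active scans) instead of block means;
* `phasewise_hr` — one task regressor and one within-phase-centered
  modulator per task phase;
* `hf_hrv` — blockwise high-frequency heart-rate-variability power as the
  modulator;
* `task_only` — per-phase task regressors with the Stress-versus-rest
  contrast `c(-1, 2, -1)`, the conventional analysis.

### Assumptions

* Volumes are already motion-corrected, spatially normalized and
  resampled to a common grid; the package starts at nuisance modelling.
* Ordinary least squares per voxel, no AR(1) prewhitening. Serial
  correlation inflates single-subject t-values but leaves the group-level
  random-effects test valid, because only per-subject effect estimates —
  independent across subjects — enter the second level. The null
  simulations in the test suite confirm nominal group-level error rates
  under AR(1) scan noise.
* The canonical double-gamma HRF is assumed to hold for all voxels; no
  temporal or dispersion derivatives are modelled.

## Paradigm and regressor construction

The default design is three phases (PreStress, Stress, PostStress) of
five 60 s active calculation blocks each followed by 40 s rest: 1500 s,
750 retained scans at TR 2 s, plus 5 discarded dummy scans (755
acquired).

Regressors are built on a microtime grid of 16 bins per TR, convolved
with the double-gamma HRF (peak delay 6 s, undershoot delay 16 s,
dispersions 1 s, peak:undershoot ratio 6, 32 s kernel, unit peak) and
sampled at scan onsets. Design choices worth spelling out:

* **Modulator centering only, no serial orthogonalization.** The
  modulator is mean-centered over the blocks in its contrast scope (all
  15 blocks for the main and volumewise models, within phase for the
  phasewise model) and *not* orthogonalized against the task regressor.
  Centering alone leaves both betas interpretable — $\beta_{task}$ as the
  response at a subject's average heart rate, $\beta_{HR}$ as the change
  per bpm — whereas serial orthogonalization would silently reassign
  shared variance to the task column.
* **Volumewise modulation rides on the task boxcar**: scan-wise heart
  rate on rest scans is ignored; only active-scan values (centered over
  active scans) modulate the boxcar.
* **Drift basis**: discrete cosines with periods at or above 256 s,
  $K = \lfloor 2 N \cdot TR / T_{cut} \rfloor$ columns with the constant
  handled separately ($K = 11$ for the default design).
* **Block-onset control**: `build_onset_control()` captures the first
  10 s (or 20 s) of every active block in a regressor of no interest
  while `trim_active_onsets()` rebuilds the task/modulator pair on the
  block remainders, to verify that onset transients do not drive
  modulator effects.

## Physiological processing

Raw PPG (BIDS physio convention, any rate) is resampled to 100 Hz with a
zero-phase spectral low-pass at 0.45 times the target rate before
interpolation. Beats are detected on the 0.5–8 Hz band-passed trace as
local maxima above an adaptive threshold (0.4 times the rolling 10 s
inter-quartile range) with a 0.3 s refractory period resolved in favour
of the larger peak.

Inter-beat intervals are artifact-filtered with a 12% tolerance: an
interval is accepted when its implied instantaneous heart rate is within
12% of the running mean of the last 50 accepted beats *or* within 12% of
the last accepted beat, and within 300–2000 ms. The last-beat clause
matters: a genuine stress transition of several bpm over a few seconds
stays within 12% beat-to-beat but can outrun a 50-beat running mean at
low baseline heart rates; with a mean-only rule rejections would freeze
the reference and cascade across whole blocks. Isolated ectopic-scale
timing errors (±50% of an interval) fail both references and are
rejected. Rejected intervals are flagged, never deleted.

Blockwise heart rate averages `60000 / interval` over accepted intervals
whose midpoints fall inside each active block (midpoint assignment is our
choice of boundary rule); volumewise heart rate linearly interpolates
instantaneous rate to scan midtimes with edge hold. HF-HRV interpolates
accepted intervals to 4 Hz (natural cubic spline), then integrates the
detrended FFT periodogram over 0.15–0.40 Hz in sliding 300 s windows
advanced by 30 s; each value sits at its window center, and block values
average the windows centered inside the block. Power is one-sided
(positive-frequency bins doubled), so disjoint bands tile the detrended
variance exactly.

The three-level visual quality rating of the original workflow is
replaced by an automated surrogate: rating 1 if under 5% of intervals are
rejected and no beat gap exceeds 3 s; rating 2 under 15% and 10 s;
rating 3 otherwise. Only rating 3 excludes a subject.

## First-level nuisance chain

1. **Motion QC**: Power-style framewise displacement (sum of absolute
   translation differences plus 50 mm times rotation differences);
   subjects with mean FD above 1.5 mm are excluded.
2. **DVARS**: RMS frame-to-frame intensity change over brain voxels,
   scaled by the median in-mask intensity; scans above the series median
   plus 1.5 IQR become one-hot spike regressors.
3. **Residualization**: every brain voxel is residualized against
   constant, linear trend, six motion parameters, their first
   differences and the spike columns; the voxel mean is added back.
4. **CompCor**: in-mask voxel series are variance-normalized and the
   first five left singular vectors of the combined WM+CSF compartment
   enter the design as nuisance columns (a switch selects five per
   tissue instead; the combined reading is the default because the model
   description counts five components total).
5. **Smoothing**: separable Gaussian, FWHM 6 mm, applied per scan with
   half-sample mirror boundaries. This boundary choice makes the 1-D
   operator symmetric and doubly stochastic, so constant images and the
   volume-wise mean are preserved exactly — useful invariants for
   testing. The kernel is truncated at 3 standard deviations.

Group inference uses voxel-level Bonferroni correction over in-mask
voxels in place of random-field-theory FWE: it requires no smoothness
estimation, is exact or conservative under any dependence, and its
control is directly verifiable by simulation (the suite checks it on 200
null cohorts). Clusters of suprathreshold voxels are formed under
18-connectivity and reported when they reach 25 voxels, with peak
coordinates mapped through the affine and Bonferroni-adjusted peak
p-values; a label volume can be attached, reporting labels covering at
least 5% of a cluster.

## Region-of-interest and behavioural analyses

ROI timecourses are the first principal component of the centered
voxels-by-time matrix, sign-aligned to the ROI mean and z-scored.
Block-locked averages cut each subject's timecourse at the active-block
onsets of one phase (100 s segments covering the block and its rest),
average within subject, and report the across-subject mean with t-based
95% confidence half-widths per timepoint (descriptive; no
multiple-timepoint correction).

Model variants are compared on per-subject mean ROI modulator betas with
Cohen's D in pooled-standard-deviation units,
$d = (\bar a - \bar b) / \sqrt{(s_a^2 + s_b^2)/2}$, accompanied by a
paired t-test because the same subjects underlie both models.

Heart-rate dynamics are summarized per subject as upswing (mean Stress
minus mean PreStress active-block HR), downswing (Stress minus
PostStress) and proportional downswing (downswing/upswing, undefined
below 0.1 bpm of upswing). Correlations with pre-to-post rating changes
are tested at alpha divided by the effective number of tests, estimated
from the rating correlation matrix by the Nyholt eigenvalue formula
$m_{eff} = 1 + (M-1)(1 - \mathrm{Var}(\lambda)/M)$; the unrounded value
is used by default (a switch rounds it), and rating changes are
post-minus-pre.

## The synthetic cohort

The study's recordings are not redistributable, so every pipeline stage
is validated on a synthetic cohort with known ground truth
(`simulate_cohort()`, `simulate_subject()`). What it emulates:

* **Heart rate**: baseline $\mathcal N(72, 8^2)$ bpm across subjects;
  +2 bpm during active blocks and a further +7 bpm during Stress active
  blocks, smoothed by an 8 s exponential onset ramp whose block-mean
  attenuation is analytically compensated, so the *injected block-mean
  elevation* is exactly the nominal value; Ornstein–Uhlenbeck wander
  (time constant 60 s, stationary sd 3 bpm); respiratory sinus
  arrhythmia at 0.25 Hz whose amplitude decreases exponentially with
  heart rate (e-folding 24 bpm, subject-level log-normal jitter sd 0.9,
  capped at 4 bpm and at 5% of the current rate). The amplitude–rate
  coupling is what produces the negative correlation between heart rate
  and HF-HRV power; the jitter sets its pooled strength near the
  mid −0.5 range, and the caps keep beat-to-beat changes inside the 12%
  artifact envelope that the pipeline itself enforces. Beats follow by
  time rescaling — integrating HR(t)/60 and placing beats at unit
  crossings — which is exact for any positive rate function.
* **PPG**: a gamma-shaped pulse at each beat, 0.2 Hz baseline wander,
  white noise at a configurable SNR (20 dB default; −20 dB renders a
  trace the quality surrogate rates unusable). Options inject sensor
  dropouts and ectopic-like beat displacements.
* **BOLD**: a 24-voxel cube at 2 mm (a deliberate desk-scale stand-in
  for a brain volume that preserves all statistical structure), with a
  spherical brain mask and five disjoint spheres: positive HR coupling
  ("insula-like"), negative HR coupling with positive task response
  ("amygdala/hippocampus-like"), task-negative ("DMN-like"), and WM and
  CSF compartments carrying shared structured noise (with a small
  gray-matter leakage) for CompCor to find. Voxel series are baseline
  100 plus HRF-convolved task (1% signal) and HR-coupled (0.08% per bpm,
  subject-level log-normal gain sd 0.3) responses, slow cosine drifts
  below the 256 s cutoff, and AR(1) noise (coefficient 0.3, sd 1%).
  Motion is a slow random walk with occasional spike frames. An optional
  block-onset transient in the negative blob supports the
  onset-control analyses.
* **Ratings**: pre-to-post changes in physical arousal and relaxation
  generated to correlate r = 0.3 (resp. −0.3) with the subject's true
  heart-rate upswing, plus positive/negative affect sum scores with
  weaker shared structure.

What it does **not** emulate: realistic vascular and respiratory fMRI
noise spectra, spatial autocorrelation of noise, anatomical geometry,
field inhomogeneity, or any endocrine measures. Passing the recovery
suite therefore demonstrates that the statistical machinery is correct
and calibrated — not that effect sizes on real data will match.

## Numerical choices and degenerate inputs

* All-zero design columns (e.g. a modulator from a constant trace) are
  dropped with a warning at assembly; rank-deficient designs are refused
  at fit time, naming the dependent columns.
* Zero across-subject variance at a voxel flags it out of group
  thresholding with a warning rather than producing infinite t.
* An upswing below 0.1 bpm makes proportional downswing `NA` (division
  guard); zero-variance rating columns are skipped.
* Blocks without accepted intervals yield `NA` block values and the
  affected subject is excluded at the pipeline level with reason
  `physio_missing_block`.
* Beat detection on a flat or constant trace returns an empty series and
  rating 3.
* Cluster peak coordinates use 0-based voxel indexing through the NIfTI
  affine.
* Simulation is deterministic: per-subject seeds are
  `master_seed + i`, and regenerating a cohort with the same master seed
  reproduces byte-identical files.

## Problem sizes used by the validation suite

The test suite and the acceptance script regenerate everything they
measure. The default imaging cohort is 20 subjects on the 24³ grid with
750 scans; blob-sign recovery is checked over 10 seeded replicates in
the tests (3 in the faster acceptance script). Error-rate control uses
200 null cohorts of 6 subjects on a 16³ grid with one block per phase
(150 scans). Physiological calibration uses 20-subject cohorts for the
HR/HF-HRV coupling and an 83-subject physiology-only cohort for the
upswing–arousal correlation. These sizes are the package's validation
conditions; they were chosen to preserve the statistical structure of
the full-scale analysis while keeping a complete validation run on a
laptop in the tens of minutes.

## Known limitations

* OLS without prewhitening makes single-subject t-values optimistic
  under serially correlated noise; group inference is unaffected, but
  single-subject maps should not be thresholded as if white.
* Bonferroni is conservative relative to random-field-theory FWE under
  heavy smoothing; reported cluster peak p-values inherit that
  conservatism.
* The quality surrogate approximates, but cannot reproduce, a visual
  rating; its thresholds (5%/15% rejected, 3 s/10 s gaps) are calibrated
  on the simulator's failure modes.
* `meff` implements the Nyholt estimator only; other effective-test
  estimators give slightly different adjusted alphas.
* The HF-HRV block trace uses windows much longer than a block (300 s vs
  60 s), so block-to-block HF variation is heavily smoothed — inherent
  to the windowing convention, and one reason the HF model is a control
  rather than the main analysis.
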