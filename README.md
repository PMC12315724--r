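# stresswave

Heart-rate-informed GLM analysis of block-design fMRI stress tasks.

Block-design psychosocial stress paradigms (Montreal-Imaging-Stress-Task
variants: mental arithmetic under social-evaluative pressure, organized
as PreStress / Stress / PostStress phases of interleaved active and rest
blocks) are usually analyzed with uniform boxcar regressors that treat
every stress block identically. But the cardiovascular stress response is
highly individual and fluctuates block by block. `stresswave` implements
the complementary analysis: the participant's own heart rate, extracted
per active block from pulse plethysmography (PPG), becomes a parametric
modulator of the task regressor, so the mass-univariate GLM finds voxels
whose BOLD signal tracks each individual's "stress wave" rather than the
experimenter's block schedule.

For scan $s$ and voxel $v$:

$$ y_v(s) = \beta_0 + \beta_{task}\,x(s) + \beta_{HR}\,m(s) +
 \gamma^\top n(s) + \varepsilon_v(s) $$

with $x$ the HRF-convolved all-blocks boxcar, $m$ the same boxcar whose
per-block heights are the mean-centered block heart rate (bpm), and $n$
nuisance terms (anatomical CompCor, discrete-cosine drift at a 256 s
cutoff, constant). Per-subject $\hat\beta_{HR}$ maps go to random-effects
one-sample t-tests in both directions with voxel-level Bonferroni
family-wise-error control and 18-connectivity cluster reporting
(extent ≥ 25 voxels).

The package covers the full chain, for whom this matters: researchers
analyzing simultaneous PPG + fMRI stress tasks who want the
heart-rate-weighted analysis next to their task-regressor model.

* **paradigm** — task timing, double-gamma HRF, task/modulator/phasewise/
  onset-control regressors, DCT drift basis, design assembly.
* **physio** — PPG resampling, beat detection, 12%/50-beat inter-beat-
  interval artifact filtering, blockwise/volumewise heart rate, sliding
  300 s / 30 s HF-HRV (0.15–0.40 Hz) spectral power, quality rating.
* **firstlevel** — framewise displacement (1.5 mm exclusion), DVARS
  spikes, motion residualization, CompCor (5 components), 6 mm Gaussian
  smoothing, voxelwise OLS with t-contrasts.
* **grouplevel** — one-sample t, Bonferroni FWE, clustering, optional
  atlas labelling.
* **roistats** — ROI first-principal-component timecourses, block-locked
  averages with 95% CIs, Cohen's D comparison of model variants on ROI
  betas.
* **behav** — heart-rate upswing/downswing metrics, correlations with
  subjective-rating changes under a Nyholt effective-number-of-tests
  correction.
* **synthdata** — a fully synthetic cohort (HR process, PPG, BOLD with
  planted couplings, motion, ratings) with known ground truth, so the
  entire pipeline is testable without any data download.

Five first-level variants sit behind one switch
(`run_config(variant=)`): `blockwise_hr` (main), `volumewise_hr`,
`phasewise_hr`, `hf_hrv`, `task_only` (phase boxcars with the
`c(-1, 2, -1)` Stress-versus-rest contrast).

## Worked example

Simulate a 12-subject cohort at the default study conditions (3×5 blocks
of 60 s + 40 s, TR 2 s, 750 scans, 24³ voxel grid with planted ±HR
couplings), run the blockwise-HR pipeline per subject, and test the
modulator at the group level:

```r
library(stresswave)

design <- build_task_design()   # 750 retained scans, 15 active blocks
cfg    <- cohort_config()       # ground-truth generator settings
rc     <- run_config()          # blockwise_hr, Bonferroni 0.05, k >= 25

recs <- list(); masks <- NULL
for (i in 1:12) {
  s <- simulate_subject(design, cfg, seed = 100 + i, with_bold = TRUE)
  recs[[i]] <- run_subject(s, design, rc)
  if (is.null(masks)) masks <- s$masks
}
g <- run_group(recs, masks$brain, rc)
g$negative$clusters
#>   label  k peak_x peak_y peak_z peak_t peak_p_fwe
#> 1     1 72    -14      0      2  -10.8      0.001
g$positive$clusters
#>   label  k peak_x peak_y peak_z peak_t peak_p_fwe
#> 1     1 67      8      0     -2   10.7    0.00102
```

The negative-direction map recovers one 72-voxel cluster centered on the
planted negative-coupling ("amygdala/hippocampus-like") sphere and the
positive map a 67-voxel cluster on the positive-coupling ("insula-like")
sphere — the planted signs, at their planted locations, surviving
voxel-level FWE. One subject's physiology from the same run:

```r
round(recs[[1]]$physio$hr_block$values, 1)
#>  [1] 71.7 70.7 74.9 75.8 73.3 80.9 79.7 77.8 77.0 78.1 73.1 73.9 72.6 73.3 71.9
swing_metrics(recs[[1]]$physio$hr_block)
#>    upswing downswing proportional_downswing
#> 1 5.423466  5.764107               1.062809
```

Block heart rates rise by ~5.4 bpm from PreStress to Stress and fall
back after — this subject's recovered stress wave (the cohort-level
injected elevation is +7 bpm).

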