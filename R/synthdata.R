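#' Configuration of the synthetic stress cohort
#'
#' Bundles every ground-truth parameter of the simulator. The defaults
#' describe a healthy-adult cohort performing the three-phase
#' calculation-stress paradigm: resting heart rate near 72 bpm with 8 bpm
#' between-subject spread, a 2 bpm elevation during active calculation
#' blocks and a further 7 bpm elevation during the Stress phase,
#' slow Ornstein-Uhlenbeck heart-rate wander, and respiratory sinus
#' arrhythmia at 0.25 Hz whose amplitude shrinks as heart rate rises
#' (vagal withdrawal), which induces the expected negative coupling
#' between heart rate and high-frequency heart-rate-variability power.
#' BOLD is rendered on a compact 24-voxel cube at 2 mm with three
#' spherical effect blobs (positive heart-rate coupling, "insula-like";
#' negative coupling, "amygdala/hippocampus-like"; task-negative,
#' "DMN-like") plus white-matter and CSF compartments carrying shared
#' structured noise for CompCor.
#'
#' @param ... Overrides for any default listed below.
#' @return A \code{cohort_config} (validated list).
#' @export
cohort_config <- function(...) {
  cfg <- list(
    # paradigm
    phases = 3, blocks_per_phase = 5, active_s = 60, rest_s = 40,
    tr = 2, n_dummy = 5,
    # heart-rate process
    baseline_bpm_mean = 72, baseline_bpm_sd = 8,
    task_bpm = 2, stress_bpm = 7,
    ou_tau_s = 60, ou_sd_bpm = 3,
    rsa_freq_hz = 0.25, rsa_amp_bpm = 2.5, rsa_hr_scale_bpm = 24,
    rsa_amp_max_bpm = 4, rsa_jitter_sd = 0.9, ramp_tau_s = 8,
    hr_dt_s = 0.1,
    # PPG rendering
    ppg_fs = 100, snr_db = 20,
    # BOLD rendering
    grid = c(24, 24, 24), voxel_mm = 2, baseline = 100,
    noise_sd = 1, ar1 = 0.3,
    task_beta_pct = 1, dmn_task_pct = -0.8,
    hr_beta_pct_per_bpm = 0.08, hr_beta_subject_sd = 0.3,
    drift_amp = 1.5, physio_leak = 0.3, transient_pct = 0,
    motion_step_mm = 0.01, spike_rate = 0.01,
    # ratings model
    rating_r_arousal = 0.3, rating_r_relax = -0.3,
    # cohort composition
    n_low_quality = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @param config A \code{cohort_config}.
#' @export
config_design <- function(config) {
  build_task_design(config$phases, config$blocks_per_phase,
                    config$active_s, config$rest_s, config$tr,
                    config$n_dummy)
}

# exponential onset/offset ramp of a 0/1 profile, time constant tau
ramp_profile <- function(x, dt, tau) {
  if (tau <= 0) return(x)
  a <- dt / tau
  y <- numeric(length(x))
  y[1] <- x[1]
  for (i in 2:length(x)) y[i] <- y[i - 1] + a * (x[i] - y[i - 1])
  y
}

#' Simulate a subject's instantaneous heart-rate process and beat times
#'
#' Heart rate is assembled as baseline + task/stress block profile
#' (smoothed with an exponential onset ramp) + Ornstein-Uhlenbeck wander +
#' a respiratory-sinus-arrhythmia sinusoid whose amplitude decreases
#' exponentially as the slow heart-rate component rises above baseline.
#' Beat times are obtained by time rescaling: the cumulative integral of
#' HR(t)/60 is inverted at unit increments, which is exact for any
#' positive rate function.
#'
#' @param design A \code{task_design}.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param baseline_bpm Optional fixed baseline (drawn from the cohort
#'   distribution when \code{NULL}).
#' @return A list: \code{times}, \code{hr} (instantaneous bpm),
#'   \code{hr_slow} (deterministic component), \code{beat_times},
#'   \code{block_hr} (true mean HR per active block, a [block_trace()]),
#'   \code{baseline_bpm}, \code{rsa_jitter}.
#' @export
simulate_hr_process <- function(design, config = cohort_config(), seed = 1,
                                baseline_bpm = NULL) {
  set.seed(seed)
  dt <- config$hr_dt_s
  total_s <- n_scans(design) * design_tr(design)
  t <- seq(0, total_s - dt, by = dt)
  if (is.null(baseline_bpm)) {
    baseline_bpm <- rnorm(1, config$baseline_bpm_mean, config$baseline_bpm_sd)
  }
  act <- active_blocks(design)
  box_task <- numeric(length(t))
  box_stress <- numeric(length(t))
  for (j in seq_len(nrow(act))) {
    sel <- t >= act$onset[j] & t < act$onset[j] + act$duration[j]
    box_task[sel] <- 1
    if (act$phase[j] == "Stress") box_stress[sel] <- 1
  }
  # the exponential onset ramp attenuates the within-block mean by a known
  # factor; compensate so task_bpm / stress_bpm are the *block-mean*
  # elevations actually injected
  T_act <- act$duration[1]
  tau <- config$ramp_tau_s
  atten <- if (tau > 0) 1 - (tau / T_act) * (1 - exp(-T_act / tau)) else 1
  prof <- (config$task_bpm / atten) *
    ramp_profile(box_task, dt, tau) +
    (config$stress_bpm / atten) * ramp_profile(box_stress, dt, tau)
  hr_slow <- baseline_bpm + prof
  # Ornstein-Uhlenbeck wander, stationary sd ou_sd_bpm
  a <- exp(-dt / config$ou_tau_s)
  eps <- rnorm(length(t), 0, config$ou_sd_bpm * sqrt(1 - a^2))
  ou <- numeric(length(t))
  ou[1] <- rnorm(1, 0, config$ou_sd_bpm)
  for (i in 2:length(t)) ou[i] <- a * ou[i - 1] + eps[i]
  # RSA with heart-rate-dependent amplitude (vagal withdrawal)
  jit <- rnorm(1, 0, config$rsa_jitter_sd)
  amp <- config$rsa_amp_bpm *
    exp(-(hr_slow + ou - config$baseline_bpm_mean) /
          config$rsa_hr_scale_bpm) * exp(jit)
  # cap: absolute, and relative to the current rate (beat-to-beat changes
  # stay well inside the 12% physiological-artifact envelope)
  amp <- pmin(amp, config$rsa_amp_max_bpm, 0.05 * (hr_slow + ou))
  phase0 <- runif(1, 0, 2 * pi)
  hr <- hr_slow + ou + amp * sin(2 * pi * config$rsa_freq_hz * t + phase0)
  bad <- hr <= 30 | hr >= 200
  if (mean(bad) > 0.01) {
    stop("simulated heart rate non-physiological (",
         round(100 * mean(bad), 1), "% of samples outside 30-200 bpm)")
  }
  hr <- pmin(pmax(hr, 31), 199)
  # time rescaling: beats at unit crossings of the integrated rate
  cum <- cumsum(hr / 60) * dt
  n_beats <- floor(max(cum))
  beat_times <- approx(cum, t, xout = seq_len(n_beats))$y
  block_hr <- vapply(seq_len(nrow(act)), function(j) {
    sel <- t >= act$onset[j] & t < act$onset[j] + act$duration[j]
    mean(hr[sel])
  }, 0)
  list(times = t, hr = hr, hr_slow = hr_slow,
       beat_times = beat_times[!is.na(beat_times)],
       block_hr = block_trace(block_hr, "bpm", phase = act$phase),
       baseline_bpm = baseline_bpm, rsa_jitter = jit)
}

#' Render a photoplethysmography trace from beat times
#'
#' Places a gamma-shaped pulse template at each beat, adds slow baseline
#' wander (0.2 Hz) and white noise at the requested signal-to-noise ratio.
#' Optionally displaces selected beats by half their local inter-beat
#' interval (ectopic-like timing artifacts) and/or silences a window of
#' the trace (sensor dropout).
#'
#' @param beat_times Beat times (s).
#' @param fs Sampling frequency (Hz, >= 50).
#' @param snr_db Signal-to-noise ratio (dB); -20 yields an unusable trace.
#' @param seed Integer seed.
#' @param duration_s Total duration (defaults to last beat + 1 s).
#' @param n_ectopic Number of beats to displace by 50\% of the local
#'   interval.
#' @param dropout_s Optional \code{c(start, end)} window to zero out.
#' @return A [physio_recording()]; displaced-beat times are attached as
#'   attribute \code{ectopic_times}.
#' @export
render_ppg <- function(beat_times, fs = 100, snr_db = 20, seed = 1,
                       duration_s = NULL, n_ectopic = 0, dropout_s = NULL) {
  stopifnot(fs >= 50, length(beat_times) >= 2)
  set.seed(seed)
  if (is.null(duration_s)) duration_s <- max(beat_times) + 1
  ect_times <- numeric(0)
  if (n_ectopic > 0) {
    nb <- length(beat_times)
    cand <- seq(10, nb - 10,
                length.out = min(n_ectopic, max(1, nb - 20)))
    idx <- unique(round(cand))
    ibi_local <- beat_times[idx + 1] - beat_times[idx]
    beat_times[idx] <- beat_times[idx] + 0.5 * ibi_local
    ect_times <- beat_times[idx]
    beat_times <- sort(beat_times)
  }
  n <- as.integer(round(duration_s * fs))
  x <- numeric(n)
  # gamma pulse template, ~0.4 s wide, peak ~0.1 s after the beat
  tt <- seq(0, 0.6, by = 1 / fs)
  tmpl <- stats::dgamma(tt, shape = 3, scale = 0.05)
  tmpl <- tmpl / max(tmpl)
  for (bt in beat_times) {
    i0 <- as.integer(round(bt * fs)) + 1L
    idx <- i0:min(n, i0 + length(tmpl) - 1L)
    if (idx[1] > n || idx[1] < 1) next
    x[idx] <- x[idx] + tmpl[seq_along(idx)]
  }
  tgrid <- (seq_len(n) - 1) / fs
  x <- x + 0.3 * sin(2 * pi * 0.2 * tgrid + runif(1, 0, 2 * pi))
  sig_pow <- mean((x - mean(x))^2)
  noise_sd <- sqrt(sig_pow / 10^(snr_db / 10))
  x <- x + rnorm(n, 0, noise_sd)
  if (!is.null(dropout_s)) {
    sel <- tgrid >= dropout_s[1] & tgrid < dropout_s[2]
    x[sel] <- 0
  }
  rec <- physio_recording(x, fs, 0, "ppg")
  attr(rec, "ectopic_times") <- ect_times
  rec
}

# sphere mask helper (voxel-index space, 1-based centers)
sphere_mask <- function(grid, center, radius) {
  co <- arrayInd(seq_len(prod(grid)), grid)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  array(d2 <= radius^2, grid)
}

# smooth random series: white noise low-passed with a moving average
smooth_series <- function(n, width) {
  as.numeric(stats::filter(rnorm(n + 2 * width), rep(1 / width, width),
                           sides = 2))[width + seq_len(n)]
}

#' Render a synthetic BOLD run with known ground truth
#'
#' Voxel series are baseline + HRF-convolved task response +
#' heart-rate-coupled response (the centered blockwise HR riding on the
#' task boxcar) + slow cosine drift + shared physiological noise + AR(1)
#' thermal noise. Effects live in three non-overlapping spherical blobs:
#' positive HR coupling ("insula-like"), negative HR coupling with a
#' positive task response ("amygdala/hippocampus-like") and a
#' task-negative blob ("DMN-like"). White-matter and CSF spheres carry the
#' shared physiological components at full strength (gray matter receives
#' a small leakage) so CompCor has structure to find.
#'
#' @param design A \code{task_design}.
#' @param hr_block A [block_trace()] of mean HR per active block (bpm).
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param hr_gain Per-subject multiplicative factor on the HR-coupling
#'   coefficients (default 1).
#' @return A list: \code{vol} ([volume4d()]), \code{masks} (brain, wm,
#'   csf, blob_pos, blob_neg, blob_dmn as [mask3d()]), \code{motion}
#'   (scans x 6), \code{truth} (3D arrays \code{task_beta},
#'   \code{hr_beta}; regressors used).
#' @export
render_bold <- function(design, hr_block, config = cohort_config(),
                        seed = 1, hr_gain = 1) {
  set.seed(seed)
  grid <- config$grid
  stopifnot(all(grid >= 16))
  ns <- n_scans(design)
  vox <- config$voxel_mm
  affine <- diag(c(vox, vox, vox, 1))
  affine[1:3, 4] <- -vox * grid / 2
  ctr <- grid / 2 + 0.5
  brain_r <- min(grid) / 2 - 1
  # blob offset and radius scale with the grid so spheres stay inside the
  # brain and pairwise disjoint (adjacent centers are offset*sqrt(2) apart)
  off <- min(5.5, brain_r - 3)
  r_blob <- min(2.5, off * sqrt(2) / 2 - 0.1, brain_r - off - 0.5)
  brain <- sphere_mask(grid, ctr, brain_r)
  blob_pos <- sphere_mask(grid, ctr + c(off, 0, 0), r_blob)
  blob_neg <- sphere_mask(grid, ctr - c(off, 0, 0), r_blob)
  blob_dmn <- sphere_mask(grid, ctr + c(0, off, 0), r_blob)
  wm <- sphere_mask(grid, ctr - c(0, off, 0), r_blob)
  csf <- sphere_mask(grid, ctr + c(0, 0, off), r_blob)
  blobs <- list(blob_pos, blob_neg, blob_dmn, wm, csf)
  for (i in seq_along(blobs)) {
    for (j in seq_along(blobs)) {
      if (i < j && any(blobs[[i]] & blobs[[j]])) {
        stop("effect/compartment blobs overlap; widen the grid")
      }
    }
  }
  hrf <- hrf_params()
  task_reg <- build_task_regressor(design, hrf)$values
  mod_reg <- build_block_modulator(design, hr_block, hrf)$values
  scl <- max(task_reg)
  task_u <- task_reg / scl        # unit-plateau task response
  mod_u <- mod_reg / scl          # bpm-scaled modulation, same units
  b <- config$baseline
  task_amp <- config$task_beta_pct / 100 * b
  dmn_amp <- config$dmn_task_pct / 100 * b
  hr_amp <- hr_gain * config$hr_beta_pct_per_bpm / 100 * b
  nv <- prod(grid)
  task_beta <- numeric(nv)
  hr_beta <- numeric(nv)
  task_beta[blob_pos | blob_neg] <- task_amp
  task_beta[blob_dmn] <- dmn_amp
  hr_beta[blob_pos] <- hr_amp
  hr_beta[blob_neg] <- -hr_amp
  # slow drifts below the high-pass cutoff, shared spatial gradient
  drift <- config$drift_amp *
    (sin(2 * pi * seq_len(ns) * design_tr(design) / 500 +
           runif(1, 0, 2 * pi)) +
       0.6 * sin(2 * pi * seq_len(ns) * design_tr(design) / 333 +
                   runif(1, 0, 2 * pi)))
  gradient <- arrayInd(seq_len(nv), grid)[, 1] / grid[1]
  # shared physiological components: strong in WM/CSF, leakage elsewhere
  n_phys <- 3
  phys <- vapply(seq_len(n_phys), function(i) smooth_series(ns, 8),
                 numeric(ns))
  load <- matrix(rnorm(n_phys * nv, 0, config$physio_leak), n_phys, nv)
  comp_idx <- which(wm | csf)
  load[, comp_idx] <- matrix(rnorm(n_phys * length(comp_idx), 0, 1.5),
                             n_phys, length(comp_idx))
  # per-row baseline and noise sd: bright AR(1) brain, dim background
  base_row <- ifelse(brain, b, 1)
  sd_row <- ifelse(brain, config$noise_sd, 0.1)
  L <- cbind(base_row, task_beta, hr_beta, gradient, t(load))
  R <- rbind(1, task_u, mod_u, drift, t(phys))
  if (config$transient_pct != 0) {
    # block-onset transient in the negative blob (Stress blocks only)
    hd <- design
    hd$kind[hd$kind == "active" & hd$phase != "Stress"] <- "rest"
    hd$duration[hd$kind == "active"] <- 6
    trans <- build_task_regressor(hd, hrf)$values / scl
    tl <- numeric(nv)
    tl[blob_neg] <- config$transient_pct / 100 * b
    L <- cbind(L, tl)
    R <- rbind(R, trans)
  }
  Y <- .bold_noise_signal(sd_row, ns, config$ar1, 0, L, R)
  dim(Y) <- c(grid, ns)
  vol <- volume4d(Y, affine, design_tr(design))
  # motion: slow random walk + occasional spikes
  motion <- vapply(seq_len(6), function(i) {
    cumsum(rnorm(ns, 0, config$motion_step_mm / ifelse(i > 3, 50, 1)))
  }, numeric(ns))
  spikes <- runif(ns) < config$spike_rate
  motion[spikes, 1] <- motion[spikes, 1] + 0.3
  truth <- list(task_beta = array(task_beta, grid),
                hr_beta = array(hr_beta, grid),
                task_regressor = task_u, hr_regressor = mod_u,
                hr_gain = hr_gain)
  list(vol = vol,
       masks = list(brain = mask3d(brain, affine),
                    wm = mask3d(wm, affine),
                    csf = mask3d(csf, affine),
                    blob_pos = mask3d(blob_pos, affine),
                    blob_neg = mask3d(blob_neg, affine),
                    blob_dmn = mask3d(blob_dmn, affine)),
       motion = motion, truth = truth)
}

#' Simulate one subject (physiology, optionally BOLD)
#'
#' @param design A \code{task_design}.
#' @param config A [cohort_config()].
#' @param seed Integer subject seed.
#' @param with_bold Render the BOLD run too? (physiology-only cohorts are
#'   much faster).
#' @param low_quality Render the PPG at -20 dB SNR (unusable trace)?
#' @return A list: \code{id}, \code{hr} (simulate_hr_process output),
#'   \code{ppg}, \code{hr_gain}, and when \code{with_bold} the
#'   [render_bold()] fields.
#' @export
simulate_subject <- function(design, config = cohort_config(), seed = 1,
                             with_bold = FALSE, low_quality = FALSE) {
  hr <- simulate_hr_process(design, config, seed = seed)
  snr <- if (low_quality) -20 else config$snr_db
  ppg <- render_ppg(hr$beat_times, fs = config$ppg_fs, snr_db = snr,
                    seed = seed + 10000L,
                    duration_s = n_scans(design) * design_tr(design))
  set.seed(seed + 20000L)
  hr_gain <- exp(rnorm(1, 0, config$hr_beta_subject_sd))
  out <- list(id = seed, hr = hr, ppg = ppg, hr_gain = hr_gain,
              low_quality = low_quality)
  if (with_bold) {
    bold <- render_bold(design, hr$block_hr, config,
                        seed = seed + 30000L, hr_gain = hr_gain)
    out <- c(out, bold)
  }
  out
}

#' Simulate a cohort with known ground truth
#'
#' Per-subject seeds are \code{master_seed + i}, making regeneration with
#' the same master seed reproducible. Physiology (heart-rate process, PPG,
#' true block traces) is always generated; BOLD runs are rendered only on
#' request (they dominate memory and runtime, and parameter-recovery runs
#' typically render them one subject at a time via [simulate_subject()]).
#' Subjective ratings are generated so that the pre-to-post change in
#' physical arousal correlates with the subject's true heart-rate upswing
#' at the configured level (default r = 0.3) and relaxation at the
#' opposite sign, alongside positive/negative affect sum scores.
#'
#' @param n_subjects Number of subjects (>= 3).
#' @param config A [cohort_config()]; \code{config$n_low_quality} subjects
#'   (spread deterministically across the cohort) get unusable -20 dB PPG.
#' @param master_seed Master seed.
#' @param with_bold Render BOLD for every subject (memory-heavy).
#' @param out_dir Optional directory: when given, writes a BIDS-like tree
#'   (events/physio/motion/ratings TSVs, NIfTI volumes when rendered, and
#'   a JSON manifest) and refuses to overwrite a non-empty directory
#'   unless \code{force}.
#' @param force Overwrite an existing non-empty \code{out_dir}.
#' @return A list: \code{design}, \code{config}, \code{subjects} (list),
#'   \code{ratings} (data frame of pre-to-post changes),
#'   \code{truth} (per-subject upswings, seeds).
#' @export
simulate_cohort <- function(n_subjects, config = cohort_config(),
                            master_seed = 1, with_bold = FALSE,
                            out_dir = NULL, force = FALSE) {
  stopifnot(n_subjects >= 3)
  design <- config_design(config)
  low_idx <- integer(0)
  if (config$n_low_quality > 0) {
    low_idx <- unique(as.integer(round(seq(1, n_subjects,
                                           length.out = config$n_low_quality))))
  }
  subjects <- lapply(seq_len(n_subjects), function(i) {
    simulate_subject(design, config, seed = master_seed + i,
                     with_bold = with_bold,
                     low_quality = i %in% low_idx)
  })
  upswing <- vapply(subjects, function(s) {
    swing_metrics(s$hr$block_hr)$upswing
  }, 0)
  set.seed(master_seed + 900000L)
  z <- as.numeric(scale(upswing))
  mix <- function(r) r * z + sqrt(1 - r^2) * rnorm(n_subjects)
  ratings <- data.frame(
    arousal_delta = 2 * mix(config$rating_r_arousal) + 3,
    relaxation_delta = 2 * mix(config$rating_r_relax) - 2,
    positive_affect_delta = 3 * (-0.4 * scale(mix(config$rating_r_relax)) +
                                   0.9 * rnorm(n_subjects)) - 2,
    negative_affect_delta = 4 * (0.4 * scale(mix(config$rating_r_arousal)) +
                                   0.9 * rnorm(n_subjects)) + 7)
  cohort <- list(design = design, config = config, subjects = subjects,
                 ratings = ratings,
                 truth = list(upswing = upswing, master_seed = master_seed,
                              seeds = master_seed + seq_len(n_subjects),
                              low_quality = low_idx))
  if (!is.null(out_dir)) write_cohort(cohort, out_dir, force = force)
  cohort
}
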