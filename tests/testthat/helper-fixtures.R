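# Shared fixtures, built in code. Heavy shared computations are cached in
# this environment so that several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# A small two-phase design for fast regressor tests: 2 phases x 2 blocks,
# 20 s active / 20 s rest, TR 2 -> 80 scans.
tiny_design <- function() {
  build_task_design(phases = 2, blocks_per_phase = 2, active_s = 20,
                    rest_s = 20, tr = 2, n_dummy = 0)
}

default_design <- function() {
  if (is.null(.fixtures$design)) .fixtures$design <- build_task_design()
  .fixtures$design
}

# Synthetic beat train at a constant rate with optional jitter (s).
constant_beats <- function(rate_bpm = 60, duration_s = 600, jitter_s = 0) {
  bt <- seq(0.5, duration_s, by = 60 / rate_bpm)
  if (jitter_s > 0) bt <- bt + rnorm(length(bt), 0, jitter_s)
  sort(bt)
}

# Boxcar sampled at scan onsets (the convolution sampling convention).
scan_onset_active <- function(design) {
  tr <- design_tr(design)
  t0 <- (seq_len(n_scans(design)) - 1) * tr
  act <- design[design$kind == "active", ]
  out <- logical(length(t0))
  for (j in seq_len(nrow(act))) {
    out <- out | (t0 >= act$onset[j] & t0 < act$onset[j] + act$duration[j])
  }
  out
}

# HRF-convolved regressor for a single active block of a design.
single_block_regressor <- function(design, which_block) {
  act_rows <- which(design$kind == "active")
  d1 <- design
  d1$kind[setdiff(act_rows, act_rows[which_block])] <- "rest"
  build_task_regressor(d1)
}

# Index of the active block containing each scan's midpoint (NA on rest).
scan_block_index <- function(design) {
  tr <- design_tr(design)
  mid <- (seq_len(n_scans(design)) - 0.5) * tr
  act <- design[design$kind == "active", ]
  out <- rep(NA_integer_, length(mid))
  for (j in seq_len(nrow(act))) {
    out[mid >= act$onset[j] & mid < act$onset[j] + act$duration[j]] <- j
  }
  out
}

active_total_duration <- function(design) {
  sum(design$duration[design$kind == "active"])
}

# Small BOLD volume with a known embedded signal for firstlevel tests.
tiny_volume <- function(n_scans = 40, dims = c(6, 6, 6), seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(prod(dims) * n_scans), c(dims, n_scans))
  volume4d(arr, diag(c(2, 2, 2, 1)), tr = 2)
}

full_mask <- function(dims = c(6, 6, 6)) {
  mask3d(array(TRUE, dims), diag(c(2, 2, 2, 1)))
}

# Default-conditions imaging cohort (n subjects), each subject simulated,
# run through the standard first-level pipeline for several model
# variants, keeping only light outputs. Cached: test files share one
# computation.
cohort_firstlevel <- function(n = 20, master_seed = 1,
                              variants = c("blockwise_hr", "volumewise_hr",
                                           "task_only")) {
  key <- paste0("fl_", n, "_", master_seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  design <- default_design()
  cfg <- cohort_config()
  rc <- run_config()
  recs <- vector("list", n)
  masks <- NULL
  for (i in seq_len(n)) {
    s <- simulate_subject(design, cfg, seed = master_seed * 1000L + i,
                          with_bold = TRUE)
    recs[[i]] <- run_subject_variants(s, design, rc, variants)
    recs[[i]]$hr_gain <- s$hr_gain
    recs[[i]]$true_block_hr <- s$hr$block_hr
    if (is.null(masks)) masks <- s$masks
  }
  out <- list(records = recs, masks = masks, design = design,
              config = cfg, run_config = rc)
  .fixtures[[key]] <- out
  out
}
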