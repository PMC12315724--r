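#' Build a block-design stress-task paradigm
#'
#' Constructs the timing of an interleaved active/rest block design split
#' into consecutive task phases (for three phases these are labelled
#' \code{PreStress}, \code{Stress}, \code{PostStress}, mirroring the
#' Montreal-Imaging-Stress-Task variant this package targets). Block onsets
#' are expressed in seconds relative to the first *retained* scan; dummy
#' scans discarded for T1 equilibration are tracked separately so the
#' acquired volume count can be reported.
#'
#' @param phases Number of task phases (default 3).
#' @param blocks_per_phase Active blocks per phase (default 5).
#' @param active_s Duration of each active block in seconds (default 60).
#' @param rest_s Duration of the rest block following each active block
#'   (default 40).
#' @param tr Repetition time in seconds (default 2).
#' @param n_dummy Leading scans acquired but discarded (default 5).
#' @return A \code{task_design} object: a data frame of blocks (columns
#'   \code{onset}, \code{duration}, \code{kind}, \code{phase}) with
#'   attributes \code{tr}, \code{n_scans}, \code{n_dummy}.
#' @examples
#' d <- build_task_design()
#' n_scans(d)              # 750 retained scans
#' sum(d$kind == "active") # 15 active blocks
#' @export
build_task_design <- function(phases = 3, blocks_per_phase = 5,
                              active_s = 60, rest_s = 40,
                              tr = 2, n_dummy = 5) {
  stopifnot(phases >= 1, blocks_per_phase >= 1, active_s > 0, rest_s > 0,
            tr > 0, n_dummy >= 0)
  total_s <- phases * blocks_per_phase * (active_s + rest_s)
  rem <- total_s %% tr
  if (abs(rem) > 1e-9) {
    stop("total task duration ", total_s, " s is not divisible by tr = ",
         tr, " s (remainder ", rem, " s)")
  }
  phase_names <- if (phases == 3) {
    c("PreStress", "Stress", "PostStress")
  } else {
    paste0("Phase", seq_len(phases))
  }
  onset <- 0
  rows <- vector("list", phases * blocks_per_phase * 2L)
  i <- 0L
  for (p in seq_len(phases)) {
    for (b in seq_len(blocks_per_phase)) {
      i <- i + 1L
      rows[[i]] <- data.frame(onset = onset, duration = active_s,
                              kind = "active", phase = phase_names[p])
      onset <- onset + active_s
      i <- i + 1L
      rows[[i]] <- data.frame(onset = onset, duration = rest_s,
                              kind = "rest", phase = phase_names[p])
      onset <- onset + rest_s
    }
  }
  blocks <- do.call(rbind, rows)
  structure(blocks,
            class = c("task_design", "data.frame"),
            tr = tr,
            n_scans = as.integer(round(total_s / tr)),
            n_dummy = as.integer(n_dummy),
            phase_names = phase_names)
}

#' @rdname build_task_design
#' @param design A \code{task_design}.
#' @export
n_scans <- function(design) attr(design, "n_scans")

#' @rdname build_task_design
#' @export
design_tr <- function(design) attr(design, "tr")

#' @rdname build_task_design
#' @export
design_phases <- function(design) attr(design, "phase_names")

active_blocks <- function(design) design[design$kind == "active", , drop = FALSE]

#' Shift active-block onsets past an initial head period
#'
#' Returns a copy of the design in which every active block starts
#' \code{head_s} seconds later with correspondingly shorter duration. Used
#' together with [build_onset_control()] so that the block-onset transient
#' can be assigned to a regressor of no interest while the task and
#' modulator regressors cover only the remainder of each block.
#'
#' @param design A \code{task_design}.
#' @param head_s Seconds to remove from the start of each active block.
#' @return A \code{task_design} with trimmed active blocks.
#' @export
trim_active_onsets <- function(design, head_s) {
  dur <- active_blocks(design)$duration
  if (head_s <= 0 || head_s >= min(dur)) {
    stop("head_s must lie strictly between 0 and the active block duration (",
         min(dur), " s)")
  }
  act <- design$kind == "active"
  design$onset[act] <- design$onset[act] + head_s
  design$duration[act] <- design$duration[act] - head_s
  design
}

#' Canonical hemodynamic response parameters
#'
#' Double-gamma HRF in the convention used throughout SPM-style analyses:
#' a gamma density peaking at \code{peak_delay} s minus a later gamma
#' undershoot scaled by \code{1/ratio}, sampled over \code{length_s}
#' seconds. Regressors are built on a microtime grid of
#' \code{microtime_bins} bins per TR before downsampling to scan times.
#'
#' @param peak_delay Delay of the response peak (s).
#' @param undershoot_delay Delay of the undershoot (s).
#' @param peak_disp,undershoot_disp Dispersions (s).
#' @param ratio Peak-to-undershoot amplitude ratio.
#' @param length_s Kernel length (s).
#' @param microtime_bins Microtime bins per TR.
#' @return An \code{hrf_params} object.
#' @export
hrf_params <- function(peak_delay = 6, undershoot_delay = 16,
                       peak_disp = 1, undershoot_disp = 1,
                       ratio = 6, length_s = 32, microtime_bins = 16) {
  stopifnot(peak_delay > 0, undershoot_delay > 0, peak_disp > 0,
            undershoot_disp > 0, ratio > 0, length_s >= undershoot_delay,
            microtime_bins >= 1)
  structure(list(peak_delay = peak_delay, undershoot_delay = undershoot_delay,
                 peak_disp = peak_disp, undershoot_disp = undershoot_disp,
                 ratio = ratio, length_s = length_s,
                 microtime_bins = microtime_bins),
            class = "hrf_params")
}

#' Sample the canonical double-gamma HRF
#'
#' @param params An [hrf_params()] object.
#' @param dt Sampling interval (s).
#' @return Numeric kernel sampled at \code{0, dt, 2 dt, ...}, normalized to
#'   unit peak.
#' @export
canonical_hrf <- function(params = hrf_params(), dt) {
  stopifnot(inherits(params, "hrf_params"), dt > 0)
  t <- seq(0, params$length_s, by = dt)
  a1 <- params$peak_delay / params$peak_disp
  a2 <- params$undershoot_delay / params$undershoot_disp
  h <- stats::dgamma(t, shape = a1, scale = params$peak_disp) -
    stats::dgamma(t, shape = a2, scale = params$undershoot_disp) / params$ratio
  h / max(h)
}

new_regressor <- function(name, values, kind) {
  structure(list(name = name, values = as.numeric(values), kind = kind),
            class = "regressor")
}

#' @export
print.regressor <- function(x, ...) {
  cat("<regressor>", x$name, sprintf("(kind = %s, %d scans)\n",
                                     x$kind, length(x$values)))
  invisible(x)
}

# Microtime support weights for the active blocks of a design.
# `block_weights` gives one height per active block (recycled boxcar height);
# `scan_weights` (length n_scans) instead assigns each scan's bins its own
# weight, restricted to active-block support. Returns the microtime vector.
microtime_boxcar <- function(design, block_weights = NULL, scan_weights = NULL,
                             mt = 16) {
  tr <- design_tr(design)
  ns <- n_scans(design)
  dt <- tr / mt
  n_micro <- ns * mt
  x <- numeric(n_micro)
  act <- active_blocks(design)
  tt <- (seq_len(n_micro) - 1) * dt
  for (j in seq_len(nrow(act))) {
    sel <- tt >= act$onset[j] & tt < act$onset[j] + act$duration[j]
    x[sel] <- if (is.null(block_weights)) 1 else block_weights[j]
  }
  if (!is.null(scan_weights)) {
    stopifnot(length(scan_weights) == ns)
    w <- rep(scan_weights, each = mt)
    x <- (x != 0) * w
  }
  x
}

# Convolve a microtime series with the HRF and sample at the first
# microtime bin of each scan.
convolve_downsample <- function(x_micro, design, hrf) {
  tr <- design_tr(design)
  mt <- hrf$microtime_bins
  k <- canonical_hrf(hrf, dt = tr / mt)
  y <- stats::convolve(x_micro, rev(k), type = "open")[seq_along(x_micro)]
  y[seq(1, length(x_micro), by = mt)]
}

#' Build the HRF-convolved task regressor
#'
#' Unit-height boxcar over every active block (irrespective of phase),
#' convolved with the canonical HRF on the microtime grid and sampled at
#' scan times.
#'
#' @param design A \code{task_design}.
#' @param hrf An [hrf_params()] object.
#' @param name Column name.
#' @return A \code{regressor} of kind \code{"task"}.
#' @export
build_task_regressor <- function(design, hrf = hrf_params(), name = "task") {
  x <- microtime_boxcar(design, mt = hrf$microtime_bins)
  new_regressor(name, convolve_downsample(x, design, hrf), "task")
}

#' Build a blockwise parametric modulator
#'
#' The boxcar height over active block *j* is the block's trace value minus
#' the mean over all active blocks (mean-centering, so the task regressor
#' retains the average response and the modulator carries only block-to-block
#' variation); the weighted boxcar is then HRF-convolved.
#'
#' @param design A \code{task_design}.
#' @param trace A [block_trace()] (or bare numeric) with one value per
#'   active block, e.g. mean heart rate in bpm.
#' @param hrf An [hrf_params()] object.
#' @param name Column name.
#' @return A \code{regressor} of kind \code{"modulator"}.
#' @export
build_block_modulator <- function(design, trace, hrf = hrf_params(),
                                  name = "hr_block") {
  v <- trace_values(trace)
  n_act <- sum(design$kind == "active")
  if (length(v) != n_act) {
    stop("trace has ", length(v), " values but the design has ", n_act,
         " active blocks")
  }
  w <- v - mean(v)
  x <- microtime_boxcar(design, block_weights = w, mt = hrf$microtime_bins)
  new_regressor(name, convolve_downsample(x, design, hrf), "modulator")
}

#' Build a volumewise parametric modulator
#'
#' The trace supplies one value per retained scan; values on scans inside
#' active blocks are mean-centered (over active scans only) and ride on the
#' task boxcar scan-by-scan; rest scans contribute nothing.
#'
#' @param design A \code{task_design}.
#' @param trace Numeric of length \code{n_scans(design)} (e.g. volumewise
#'   heart rate, bpm).
#' @param hrf An [hrf_params()] object.
#' @param name Column name.
#' @return A \code{regressor} of kind \code{"modulator"}.
#' @export
build_volume_modulator <- function(design, trace, hrf = hrf_params(),
                                   name = "hr_volume") {
  v <- trace_values(trace)
  ns <- n_scans(design)
  if (length(v) != ns) {
    stop("trace has ", length(v), " values but the design retains ", ns,
         " scans")
  }
  act_scan <- scan_is_active(design)
  w <- numeric(ns)
  w[act_scan] <- v[act_scan] - mean(v[act_scan])
  x <- microtime_boxcar(design, scan_weights = w, mt = hrf$microtime_bins)
  new_regressor(name, convolve_downsample(x, design, hrf), "modulator")
}

#' Which retained scans fall inside active blocks?
#'
#' A scan is active when its mid-acquisition time lies inside an active
#' block.
#'
#' @param design A \code{task_design}.
#' @return Logical vector of length \code{n_scans(design)}.
#' @export
scan_is_active <- function(design) {
  tr <- design_tr(design)
  mid <- (seq_len(n_scans(design)) - 0.5) * tr
  act <- active_blocks(design)
  out <- logical(length(mid))
  for (j in seq_len(nrow(act))) {
    out <- out | (mid >= act$onset[j] & mid < act$onset[j] + act$duration[j])
  }
  out
}

#' Per-phase task regressors and (optionally) within-phase modulators
#'
#' One boxcar regressor per task phase supports the task-regressor-based
#' model with its Stress-versus-rest-phases contrast \code{c(-1, 2, -1)};
#' when a blockwise trace is supplied a per-phase modulator is added whose
#' centering is *within phase*, mirroring the contrast scope of the
#' phasewise control model.
#'
#' @param design A \code{task_design}.
#' @param trace Optional blockwise trace (one value per active block).
#' @param hrf An [hrf_params()] object.
#' @return A list of \code{regressor}s (tasks first, then modulators).
#' @export
build_phasewise_regressors <- function(design, trace = NULL,
                                       hrf = hrf_params()) {
  phases <- design_phases(design)
  act <- active_blocks(design)
  v <- if (!is.null(trace)) trace_values(trace)
  out <- list()
  for (ph in phases) {
    in_ph <- act$phase == ph
    w <- as.numeric(in_ph)
    x <- microtime_boxcar(design, block_weights = w, mt = hrf$microtime_bins)
    out[[length(out) + 1L]] <-
      new_regressor(paste0("task_", ph), convolve_downsample(x, design, hrf),
                    "task")
  }
  if (!is.null(v)) {
    stopifnot(length(v) == nrow(act))
    for (ph in phases) {
      in_ph <- act$phase == ph
      w <- numeric(nrow(act))
      w[in_ph] <- v[in_ph] - mean(v[in_ph])
      x <- microtime_boxcar(design, block_weights = w, mt = hrf$microtime_bins)
      out[[length(out) + 1L]] <-
        new_regressor(paste0("hr_", ph), convolve_downsample(x, design, hrf),
                      "modulator")
    }
  }
  out
}

#' Regressor of no interest for the block-onset transient
#'
#' An HRF-convolved boxcar covering only the first \code{head_s} seconds of
#' each active block, used to check that block-onset artifacts (transient
#' arousal, perfusion or motion responses) do not drive modulator effects.
#' Pair it with regressors rebuilt on [trim_active_onsets()] output.
#'
#' @param design A \code{task_design}.
#' @param head_s Seconds of each active block to capture (must be strictly
#'   between 0 and the active block duration; 10 or 20 are typical).
#' @param hrf An [hrf_params()] object.
#' @return A \code{regressor} of kind \code{"control"}.
#' @export
build_onset_control <- function(design, head_s, hrf = hrf_params()) {
  act <- active_blocks(design)
  if (head_s <= 0 || head_s >= min(act$duration)) {
    stop("head_s must lie strictly between 0 and the active block duration (",
         min(act$duration), " s)")
  }
  head_design <- design
  sel <- head_design$kind == "active"
  head_design$duration[sel] <- head_s
  x <- microtime_boxcar(head_design, mt = hrf$microtime_bins)
  new_regressor(paste0("onset_", head_s, "s"),
                convolve_downsample(x, head_design, hrf), "control")
}

#' Discrete-cosine high-pass drift basis
#'
#' Drift columns with periods no shorter than \code{cutoff_s}; the number of
#' columns is \code{K = floor(2 * n_scans * tr / cutoff_s)} and the constant
#' term is *excluded* (it is added by [assemble_design()]).
#'
#' @param n_scans Number of retained scans.
#' @param tr Repetition time (s).
#' @param cutoff_s High-pass cutoff period (s); 256 s by default.
#' @return A list of \code{regressor}s of kind \code{"drift"} (possibly
#'   empty).
#' @export
dct_highpass_basis <- function(n_scans, tr, cutoff_s = 256) {
  if (cutoff_s <= 2 * tr) {
    stop("cutoff_s must exceed 2 * tr = ", 2 * tr, " s")
  }
  K <- floor(2 * n_scans * tr / cutoff_s)
  if (K < 1) return(list())
  n <- n_scans
  t <- seq_len(n) - 1
  lapply(seq_len(K), function(k) {
    v <- sqrt(2 / n) * cos(pi * (2 * t + 1) * k / (2 * n))
    new_regressor(sprintf("dct_%03d", k), v, "drift")
  })
}

#' Assemble a first-level design matrix
#'
#' Orders columns task, modulator, control, nuisance, drift, constant;
#' records column metadata and the matrix rank. All-zero columns (e.g. a
#' modulator built from a constant trace) are dropped with a warning, and a
#' unit constant column is always appended.
#'
#' @param regressors A list of \code{regressor}s (task/modulator/control/
#'   drift); must be non-empty.
#' @param nuisance Optional \code{nuisance_set} (see
#'   [build_nuisance_set()]) or a plain numeric matrix of nuisance columns.
#' @param tr Repetition time (s), stored as metadata.
#' @return A \code{design_matrix}: list with \code{X} (scans x columns),
#'   \code{meta} (name, kind per column), \code{tr}, \code{rank}.
#' @export
assemble_design <- function(regressors, nuisance = NULL, tr = NULL) {
  if (length(regressors) == 0) stop("no regressors supplied")
  if (inherits(regressors, "regressor")) regressors <- list(regressors)
  kinds <- vapply(regressors, function(r) r$kind, "")
  ord <- order(match(kinds, c("task", "modulator", "control", "drift")))
  regressors <- regressors[ord]
  kinds <- kinds[ord]
  ns <- unique(vapply(regressors, function(r) length(r$values), 0L))
  if (length(ns) != 1) stop("regressors differ in length: ",
                            paste(ns, collapse = ", "))
  main <- kinds != "drift"
  X <- vapply(regressors[main], function(r) r$values, numeric(ns))
  meta <- data.frame(name = vapply(regressors[main], function(r) r$name, ""),
                     kind = kinds[main])
  nuis_mat <- nuisance_columns(nuisance, ns)
  if (!is.null(nuis_mat)) {
    X <- cbind(X, nuis_mat)
    meta <- rbind(meta, data.frame(name = colnames(nuis_mat),
                                   kind = "nuisance"))
  }
  if (any(!main)) {
    X <- cbind(X, vapply(regressors[!main], function(r) r$values,
                         numeric(ns)))
    meta <- rbind(meta,
                  data.frame(name = vapply(regressors[!main],
                                           function(r) r$name, ""),
                             kind = "drift"))
  }
  zero <- apply(X, 2, function(v) all(abs(v) < 1e-12))
  if (any(zero)) {
    warning("dropping all-zero column(s): ",
            paste(meta$name[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    meta <- meta[!zero, , drop = FALSE]
  }
  X <- cbind(X, constant = 1)
  meta <- rbind(meta, data.frame(name = "constant", kind = "constant"))
  if (anyDuplicated(meta$name)) {
    stop("duplicate column names: ",
         paste(unique(meta$name[duplicated(meta$name)]), collapse = ", "))
  }
  colnames(X) <- meta$name
  structure(list(X = X, meta = meta, tr = tr, rank = qr(X)$rank),
            class = "design_matrix")
}

nuisance_columns <- function(nuisance, n) {
  if (is.null(nuisance)) return(NULL)
  if (inherits(nuisance, "nuisance_set")) {
    nuisance <- nuisance_matrix(nuisance)
  }
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != n) {
    stop("nuisance columns have ", nrow(nuisance), " rows, expected ", n)
  }
  if (is.null(colnames(nuisance))) {
    colnames(nuisance) <- paste0("nuisance_", seq_len(ncol(nuisance)))
  }
  nuisance
}

#' @export
print.design_matrix <- function(x, ...) {
  cat("<design_matrix>", nrow(x$X), "scans x", ncol(x$X), "columns, rank",
      x$rank, "\n")
  print(table(x$meta$kind))
  invisible(x)
}

#' Read / write BIDS-style events tables
#'
#' Events are stored as tab-separated text with columns \code{onset},
#' \code{duration}, \code{trial_type} (\code{active}/\code{rest}) and
#' \code{phase}; onsets are seconds relative to the first retained scan.
#'
#' @param design A \code{task_design}.
#' @param path File path (.tsv).
#' @export
write_events_tsv <- function(design, path) {
  df <- data.frame(onset = design$onset, duration = design$duration,
                   trial_type = design$kind, phase = design$phase)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param tr,n_dummy Scan timing metadata to attach (the TSV itself carries
#'   only block timing).
#' @export
read_events_tsv <- function(path, tr = 2, n_dummy = 5) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type", "phase") %in% names(df)))
  total_s <- max(df$onset + df$duration)
  blocks <- data.frame(onset = df$onset, duration = df$duration,
                       kind = df$trial_type, phase = df$phase)
  structure(blocks, class = c("task_design", "data.frame"), tr = tr,
            n_scans = as.integer(round(total_s / tr)),
            n_dummy = as.integer(n_dummy),
            phase_names = unique(df$phase))
}
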