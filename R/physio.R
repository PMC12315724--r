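#' Physiological recording container
#'
#' A continuous single-channel physiological trace (here: finger
#' photoplethysmography) with its sampling frequency and start time
#' relative to the first retained scan.
#'
#' @param samples Numeric samples (a.u.); must be finite and non-empty.
#' @param fs Sampling frequency (Hz).
#' @param start_offset Time of the first sample in seconds relative to the
#'   first retained scan (default 0).
#' @param channel Channel label.
#' @return A \code{physio_recording} object.
#' @export
physio_recording <- function(samples, fs, start_offset = 0,
                             channel = "ppg") {
  stopifnot(fs > 0, length(samples) > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_offset = start_offset, channel = channel),
            class = "physio_recording")
}

#' @export
print.physio_recording <- function(x, ...) {
  cat(sprintf("<physio_recording> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Resample a physiological recording
#'
#' Anti-aliased resampling: when downsampling, the signal is first
#' low-pass filtered with a zero-phase spectral (FFT) filter at
#' \code{0.45 * fs_target}, then interpolated onto the target grid; when
#' upsampling it is spline-interpolated directly. Duration is preserved to
#' within one sample.
#'
#' @param rec A [physio_recording()].
#' @param fs_target Target sampling frequency (Hz).
#' @return A resampled \code{physio_recording}.
#' @export
resample_physio <- function(rec, fs_target) {
  stopifnot(inherits(rec, "physio_recording"), fs_target > 0)
  if (abs(fs_target - rec$fs) < 1e-12) return(rec)
  x <- rec$samples
  n <- length(x)
  if (fs_target < rec$fs) {
    cutoff <- 0.45 * fs_target
    X <- fft(x)
    freq <- (seq_len(n) - 1) / n * rec$fs
    freq <- pmin(freq, rec$fs - freq)  # two-sided
    X[freq > cutoff] <- 0
    x <- Re(fft(X, inverse = TRUE)) / n
  }
  t_old <- (seq_len(n) - 1) / rec$fs
  n_new <- max(2L, as.integer(round(n * fs_target / rec$fs)))
  t_new <- (seq_len(n_new) - 1) / fs_target
  t_new <- t_new[t_new <= t_old[n] + 1e-12]
  y <- if (fs_target < rec$fs) {
    approx(t_old, x, xout = t_new, rule = 2)$y
  } else {
    spline(t_old, x, xout = t_new)$y
  }
  physio_recording(y, fs_target, rec$start_offset, rec$channel)
}

#' Detect pulse peaks in a PPG recording
#'
#' The trace is band-pass filtered (0.5-8 Hz, zero-phase Butterworth) to
#' isolate pulse morphology, then local maxima exceeding an adaptive
#' threshold (0.4 times the rolling 10 s inter-quartile range of the
#' filtered signal) are kept, with a 0.3 s refractory period resolved in
#' favour of the larger peak. A quality surrogate for visual trace rating
#' is attached: rating 1 if the inter-beat-interval artifact filter rejects
#' under 5\% of intervals and the longest beat gap is under 3 s, rating 2
#' under 15\% and 10 s, rating 3 otherwise (traces rated 3 are considered
#' unusable).
#'
#' @param rec A [physio_recording()], typically at 100 Hz.
#' @param band Pass band (Hz).
#' @param refractory_s Minimum beat separation (s).
#' @param threshold_scale Threshold as a multiple of the rolling IQR.
#' @return A list with \code{beats} (a \code{beat_series}: numeric beat
#'   times in s, strictly increasing) and \code{quality} (a
#'   \code{quality_report}: \code{rating}, \code{rejected_fraction},
#'   \code{longest_gap_s}).
#' @export
detect_beats <- function(rec, band = c(0.5, 8), refractory_s = 0.3,
                         threshold_scale = 0.4) {
  stopifnot(inherits(rec, "physio_recording"))
  fs <- rec$fs
  x <- rec$samples
  n <- length(x)
  dur <- n / fs
  if (stats::sd(x) < 1e-12 || n < fs) {
    return(list(beats = beat_series(numeric(0)),
                quality = quality_report(3, 1, dur)))
  }
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  # rolling 10 s IQR, piecewise constant per chunk
  chunk <- max(1L, as.integer(round(10 * fs)))
  starts <- seq(1L, n, by = chunk)
  iqr_chunk <- vapply(starts, function(s) {
    IQR(xf[s:min(n, s + chunk - 1L)])
  }, 0)
  thr <- rep(threshold_scale * iqr_chunk,
             times = diff(c(starts, n + 1L)))
  # strict local maxima above threshold
  cand <- which(xf[c(-1, -n)] > xf[seq_len(n - 2)] &
                  xf[c(-1, -n)] >= xf[-(1:2)]) + 1L
  cand <- cand[xf[cand] > thr[cand] & thr[cand] > 0]
  # refractory: greedy by peak height
  keep <- logical(length(cand))
  if (length(cand)) {
    taken <- numeric(0)
    for (i in order(xf[cand], decreasing = TRUE)) {
      t_i <- cand[i] / fs
      if (!length(taken) || min(abs(taken - t_i)) >= refractory_s) {
        keep[i] <- TRUE
        taken <- c(taken, t_i)
      }
    }
  }
  idx <- sort(cand[keep])
  beat_t <- (idx - 1) / fs + rec$start_offset
  beats <- beat_series(beat_t)
  if (length(beat_t) < 2) {
    return(list(beats = beats, quality = quality_report(3, 1, dur)))
  }
  ib <- filter_ibis(beats)
  rej <- mean(!ib$accepted)
  t0 <- rec$start_offset
  gaps <- c(beat_t[1] - t0, diff(beat_t), t0 + dur - beat_t[length(beat_t)])
  gap <- max(gaps)
  rating <- if (rej < 0.05 && gap < 3) 1L else if (rej < 0.15 && gap < 10) 2L else 3L
  list(beats = beats, quality = quality_report(rating, rej, gap))
}

beat_series <- function(beat_times) {
  stopifnot(!is.unsorted(beat_times, strictly = TRUE))
  structure(list(beat_times = as.numeric(beat_times)), class = "beat_series")
}

quality_report <- function(rating, rejected_fraction, longest_gap_s) {
  structure(list(rating = as.integer(rating),
                 rejected_fraction = rejected_fraction,
                 longest_gap_s = longest_gap_s),
            class = "quality_report")
}

#' Artifact-filter inter-beat intervals
#'
#' Converts beat times to successive inter-beat intervals and flags
#' non-physiological jumps: an interval is accepted when its implied
#' instantaneous heart rate is within \code{tolerance} (default 12\%) of
#' either the running mean heart rate of the last \code{window} (default
#' 50) accepted beats or the last accepted beat's rate, *and* the
#' interval lies within physiological bounds (300-2000 ms). The
#' last-beat comparison lets genuine smooth accelerations (stress onsets)
#' through while isolated ectopic-scale jumps fail both references.
#' Rejected intervals are flagged, never deleted, so downstream averaging
#' can skip them while beat timing is preserved.
#'
#' @param beats A \code{beat_series} (or bare numeric of beat times, s).
#' @param tolerance Allowed fractional deviation of the instantaneous HR
#'   from the running mean (default 0.12).
#' @param window Number of recent accepted beats in the running mean
#'   (default 50).
#' @param bounds_ms Physiological interval bounds in ms.
#' @return An \code{ibi_series}: list with \code{beat_times},
#'   \code{interval_ms}, \code{accepted} (one flag per interval).
#' @export
filter_ibis <- function(beats, tolerance = 0.12, window = 50,
                        bounds_ms = c(300, 2000)) {
  stopifnot(tolerance > 0, tolerance < 1, window >= 1)
  bt <- if (inherits(beats, "beat_series")) beats$beat_times else beats
  if (length(bt) < 2) {
    return(structure(list(beat_times = bt, interval_ms = numeric(0),
                          accepted = logical(0)), class = "ibi_series"))
  }
  ibi <- diff(bt) * 1000
  hr <- 60000 / ibi
  acc <- logical(length(ibi))
  buf <- numeric(0)
  for (i in seq_along(ibi)) {
    in_bounds <- ibi[i] >= bounds_ms[1] && ibi[i] <= bounds_ms[2]
    if (!length(buf)) {
      ok <- in_bounds
    } else {
      ref <- mean(tail(buf, window))
      last <- buf[length(buf)]
      ok <- in_bounds && (abs(hr[i] - ref) <= tolerance * ref ||
                            abs(hr[i] - last) <= tolerance * last)
    }
    if (ok) {
      acc[i] <- TRUE
      buf <- c(tail(buf, window - 1), hr[i])
    }
  }
  structure(list(beat_times = bt, interval_ms = ibi, accepted = acc),
            class = "ibi_series")
}

#' @export
print.ibi_series <- function(x, ...) {
  cat(sprintf("<ibi_series> %d intervals, %.1f%% accepted\n",
              length(x$interval_ms), 100 * mean(x$accepted)))
  invisible(x)
}

ibi_midpoints <- function(ibis) {
  ibis$beat_times[-length(ibis$beat_times)] + ibis$interval_ms / 2000
}

#' Blockwise trace container
#'
#' One physiological value per active block, the payload of the blockwise
#' parametric modulator.
#'
#' @param values Numeric, one per active block.
#' @param units Unit label ("bpm" or "ms2").
#' @param phase Optional phase label per block.
#' @return A \code{block_trace}.
#' @export
block_trace <- function(values, units = "bpm", phase = NULL) {
  structure(list(values = as.numeric(values), units = units, phase = phase),
            class = "block_trace")
}

trace_values <- function(x) {
  if (inherits(x, "block_trace")) x$values else as.numeric(x)
}

#' Mean heart rate per active block
#'
#' Averages instantaneous heart rate (60000 / interval ms) over accepted
#' intervals whose midpoints fall inside each active block. Blocks without
#' any accepted interval yield \code{NA} with a warning; whether to exclude
#' such a subject is a pipeline-level decision.
#'
#' @param ibis An [filter_ibis()] result.
#' @param design A \code{task_design}.
#' @return A [block_trace()] in bpm with per-block phase labels.
#' @export
hr_block_means <- function(ibis, design) {
  act <- active_blocks(design)
  mid <- ibi_midpoints(ibis)
  hr <- 60000 / ibis$interval_ms
  vals <- vapply(seq_len(nrow(act)), function(j) {
    sel <- ibis$accepted & mid >= act$onset[j] &
      mid < act$onset[j] + act$duration[j]
    if (!any(sel)) NA_real_ else mean(hr[sel])
  }, 0)
  if (anyNA(vals)) {
    warning("no accepted intervals in active block(s) ",
            paste(which(is.na(vals)), collapse = ", "))
  }
  block_trace(vals, "bpm", phase = act$phase)
}

#' Volumewise heart rate
#'
#' Instantaneous heart rate at accepted-interval midpoints, linearly
#' interpolated to scan mid-acquisition times; scans outside beat coverage
#' take the nearest value (edge hold) with a warning.
#'
#' @param ibis An [filter_ibis()] result.
#' @param design A \code{task_design}.
#' @return Numeric vector, one bpm value per retained scan.
#' @export
hr_volume_means <- function(ibis, design) {
  mid <- ibi_midpoints(ibis)[ibis$accepted]
  hr <- (60000 / ibis$interval_ms)[ibis$accepted]
  if (length(hr) < 2) stop("need at least 2 accepted intervals")
  tr <- design_tr(design)
  scan_t <- (seq_len(n_scans(design)) - 0.5) * tr
  if (min(scan_t) < min(mid) || max(scan_t) > max(mid)) {
    warning("scan times outside beat coverage; edge values held")
  }
  approx(mid, hr, xout = scan_t, rule = 2)$y
}

#' Sliding-window high-frequency heart-rate-variability power
#'
#' The accepted inter-beat intervals are cubic-spline interpolated to an
#' evenly sampled series (default 4 Hz), then for each window (default
#' 300 s, advanced in 30 s steps) the series is linearly detrended and the
#' FFT periodogram integrated over the high-frequency band (default
#' 0.15-0.40 Hz). Each power value is assigned to the window center.
#'
#' @param ibis An [filter_ibis()] result.
#' @param band Frequency band (Hz).
#' @param window_s Window length (s).
#' @param shift_s Window step (s).
#' @param resample_hz Interpolation rate (Hz).
#' @return A \code{window_trace}: list with \code{times} (window centers,
#'   s) and \code{values} (band power, ms^2).
#' @export
hf_hrv <- function(ibis, band = c(0.15, 0.40), window_s = 300,
                   shift_s = 30, resample_hz = 4) {
  mid <- ibi_midpoints(ibis)[ibis$accepted]
  y <- ibis$interval_ms[ibis$accepted]
  span <- diff(range(mid))
  if (span < window_s) {
    stop("recording spans ", round(span, 1), " s but at least ", window_s,
         " s are required for one window")
  }
  grid <- seq(min(mid), max(mid), by = 1 / resample_hz)
  yi <- spline(mid, y, xout = grid, method = "natural")$y
  centers <- seq(min(mid) + window_s / 2, max(mid) - window_s / 2,
                 by = shift_s)
  vals <- vapply(centers, function(ct) {
    sel <- grid >= ct - window_s / 2 & grid < ct + window_s / 2
    band_power(yi[sel], resample_hz, band)
  }, 0)
  structure(list(times = centers, values = vals, units = "ms2",
                 band = band), class = "window_trace")
}

# Integrated periodogram power of a detrended segment in [band[1], band[2]]
# Hz. One-sided convention: positive-frequency bins count twice (Nyquist
# once), so that disjoint bands tiling (0, fs/2] sum to the segment
# variance (Parseval).
band_power <- function(y, fs, band) {
  n <- length(y)
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), y)
  y <- fit$residuals
  X <- fft(y)
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq > 0 & freq <= fs / 2 + 1e-12
  w <- ifelse(abs(freq - fs / 2) < 1e-12, 1, 2)
  sel <- half & freq >= band[1] & freq <= band[2]
  sum(w[sel] * Mod(X[sel])^2) / n^2
}

#' Average window-trace values per active block
#'
#' Block value = mean of sliding-window values whose centers fall in the
#' block; blocks containing no window center get \code{NA}.
#'
#' @param wt A \code{window_trace} from [hf_hrv()].
#' @param design A \code{task_design}.
#' @return A [block_trace()] in the window trace's units.
#' @export
window_block_means <- function(wt, design) {
  act <- active_blocks(design)
  vals <- vapply(seq_len(nrow(act)), function(j) {
    sel <- wt$times >= act$onset[j] & wt$times < act$onset[j] + act$duration[j]
    if (!any(sel)) NA_real_ else mean(wt$values[sel])
  }, 0)
  block_trace(vals, wt$units, phase = act$phase)
}

#' Pooled correlation between heart rate and HF-HRV block traces
#'
#' Pearson correlation over all subject-by-block pairs. Optionally the HF
#' power can be log-transformed first (spectral powers are strongly
#' right-skewed); the default correlates raw power.
#'
#' @param hr_list,hf_list Lists of [block_trace()]s, one per subject, with
#'   matching block structure.
#' @param log_hf Log-transform HF power first? Default \code{FALSE}.
#' @return Pearson r (scalar); \code{NA} with a warning when either pooled
#'   vector is constant.
#' @export
hr_hf_correlation <- function(hr_list, hf_list, log_hf = FALSE) {
  stopifnot(length(hr_list) == length(hf_list))
  hr <- unlist(lapply(hr_list, trace_values))
  hf <- unlist(lapply(hf_list, trace_values))
  stopifnot(length(hr) == length(hf))
  ok <- is.finite(hr) & is.finite(hf) & hf > 0
  hr <- hr[ok]
  hf <- if (log_hf) log(hf[ok]) else hf[ok]
  if (stats::sd(hr) < 1e-12 || stats::sd(hf) < 1e-12) {
    warning("zero variance in pooled trace; correlation undefined")
    return(NA_real_)
  }
  cor(hr, hf)
}
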