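#' First principal component timecourse of a region of interest
#'
#' The first left singular vector of the voxel-centered in-ROI
#' voxels-by-time matrix, sign-aligned to correlate positively with the
#' ROI mean series and z-scored. Summarizes the dominant shared signal of
#' the region in one timecourse per subject.
#'
#' @param vol A [volume4d()] (preprocessed).
#' @param roi A [mask3d()].
#' @return Numeric z-scored timecourse of length \code{n} scans.
#' @export
roi_first_pc <- function(vol, roi) {
  Y <- mask_timeseries(vol, roi)            # scans x voxels
  Y <- sweep(Y, 2, colMeans(Y))
  if (max(abs(Y)) < 1e-12) stop("ROI has zero variance")
  sv <- svd(Y, nu = 1, nv = 0)
  pc <- sv$u[, 1] * sv$d[1]
  mean_ts <- rowMeans(Y)
  if (stats::sd(mean_ts) > 0 && cor(pc, mean_ts) < 0) pc <- -pc
  as.numeric(scale(pc))
}

#' Block-locked average timecourse with confidence band
#'
#' For each subject, the z-scored ROI timecourse is cut into segments
#' locked to the active-block onsets of one task phase (covering the
#' active block plus the following rest block) and averaged over that
#' phase's blocks; across subjects, the mean and a t-based 95\% confidence
#' half-width are returned per timepoint.
#'
#' @param tcs List of per-subject timecourses (length \code{n_scans}).
#' @param design A \code{task_design}.
#' @param phase Phase label present in the design.
#' @param conf Confidence level (default 0.95).
#' @return A data frame: \code{time} (s from block onset), \code{mean},
#'   \code{ci_halfwidth}, plus attributes \code{phase} and \code{n}.
#' @export
block_locked_average <- function(tcs, design, phase, conf = 0.95) {
  stopifnot(length(tcs) >= 2)
  if (!phase %in% design$phase) stop("phase '", phase, "' not in design")
  tr <- design_tr(design)
  act <- active_blocks(design)
  act <- act[act$phase == phase, , drop = FALSE]
  rest_s <- design$duration[design$kind == "rest"][1]
  seg_len <- as.integer(round((act$duration[1] + rest_s) / tr))
  per_subject <- vapply(tcs, function(tc) {
    segs <- vapply(seq_len(nrow(act)), function(j) {
      s0 <- as.integer(round(act$onset[j] / tr))
      idx <- s0 + seq_len(seg_len)
      idx <- idx[idx <= length(tc)]
      out <- rep(NA_real_, seg_len)
      out[seq_along(idx)] <- tc[idx]
      out
    }, numeric(seg_len))
    rowMeans(segs, na.rm = TRUE)
  }, numeric(seg_len))                       # timepoints x subjects
  n <- ncol(per_subject)
  mu <- rowMeans(per_subject)
  se <- apply(per_subject, 1, stats::sd) / sqrt(n)
  hw <- qt(1 - (1 - conf) / 2, n - 1) * se
  structure(data.frame(time = (seq_len(seg_len) - 1) * tr, mean = mu,
                       ci_halfwidth = hw),
            phase = phase, n = n)
}

#' Mean contrast effect inside a region of interest, per subject
#'
#' @param maps List of per-subject \code{contrast_map}s (or 3D effect
#'   arrays).
#' @param roi A [mask3d()] (a bilateral mask union for bilateral ROIs).
#' @return Numeric vector of per-subject mean in-ROI effects.
#' @export
extract_roi_betas <- function(maps, roi) {
  vapply(maps, function(m) {
    a <- if (inherits(m, "contrast_map")) m$effect else m
    v <- a[roi$mask]
    v <- v[is.finite(v)]
    if (!length(v)) stop("ROI does not intersect the map support")
    mean(v)
  }, 0)
}

#' Cohen's D between two model variants on ROI betas
#'
#' Effect size of the difference in mean ROI beta coefficients between two
#' model variants fitted on the same subjects, in pooled-standard-deviation
#' units: \code{d = (mean_a - mean_b) / sqrt((var_a + var_b) / 2)}, with a
#' paired t-test p-value on the per-subject differences (the same subjects
#' underlie both models).
#'
#' @param betas_a,betas_b Per-subject mean ROI betas for the two variants.
#' @param roi,model_a,model_b Labels carried into the output.
#' @return A one-row data frame: \code{roi}, \code{model_a},
#'   \code{model_b}, \code{d}, \code{p}, \code{stars}.
#' @export
cohens_d_models <- function(betas_a, betas_b, roi = "roi",
                            model_a = "a", model_b = "b") {
  stopifnot(length(betas_a) == length(betas_b), length(betas_a) >= 3)
  pooled <- sqrt((var(betas_a) + var(betas_b)) / 2)
  diffs <- betas_a - betas_b
  if (pooled < 1e-12) {
    d <- 0
    p <- NA_real_
  } else {
    d <- (mean(betas_a) - mean(betas_b)) / pooled
    p <- if (stats::sd(diffs) < 1e-12) NA_real_ else
      t.test(diffs)$p.value
  }
  stars <- if (is.na(p)) "" else if (p < 0.001) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
  data.frame(roi = roi, model_a = model_a, model_b = model_b,
             d = d, p = p, stars = stars)
}
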