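#' First-level analysis configuration
#'
#' Validated bundle of every tunable the pipeline uses; unknown fields are
#' rejected. The defaults reproduce the package's reference analysis:
#' blockwise heart rate as the parametric modulator, 256 s discrete-cosine
#' high-pass, five CompCor components from the combined WM+CSF
#' compartments, 6 mm smoothing, Bonferroni voxel-level FWE at 0.05 with a
#' 25-voxel cluster extent, and a 1.5 mm mean-FD motion exclusion
#' threshold.
#'
#' @param ... Overrides for the defaults listed below.
#' @return A \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(
    variant = "blockwise_hr",
    alpha = 0.05, extent_k = 25, connectivity = 18,
    fd_limit_mm = 1.5, fd_radius_mm = 50,
    highpass_s = 256, fwhm_mm = 6,
    n_compcor = 5, compcor_per_tissue = FALSE,
    hrf = hrf_params(),
    onset_control_s = NULL,
    ibi_tolerance = 0.12, ibi_window = 50,
    hf_band = c(0.15, 0.40), hf_window_s = 300, hf_shift_s = 30,
    smooth = TRUE, residualize = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  variants <- c("blockwise_hr", "volumewise_hr", "phasewise_hr", "hf_hrv",
                "task_only")
  if (!cfg$variant %in% variants) {
    stop("variant must be one of: ", paste(variants, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Extract the per-block / per-scan physiological traces of a subject
#'
#' Runs the physiological chain (beat detection, inter-beat-interval
#' artifact filtering, HR / HF-HRV extraction) on a subject's PPG.
#'
#' @param ppg A [physio_recording()] (100 Hz convention).
#' @param design A \code{task_design}.
#' @param config A [run_config()].
#' @return A list: \code{quality}, \code{ibis}, \code{hr_block},
#'   \code{hr_volume}, \code{hf_block} (HF only when the variant needs
#'   it).
#' @export
subject_physio <- function(ppg, design, config = run_config()) {
  det <- detect_beats(ppg)
  if (det$quality$rating >= 3) {
    return(list(quality = det$quality, ibis = NULL))
  }
  ibis <- filter_ibis(det$beats, tolerance = config$ibi_tolerance,
                      window = config$ibi_window)
  hr_block <- hr_block_means(ibis, design)
  out <- list(quality = det$quality, ibis = ibis, hr_block = hr_block,
              hr_volume = NULL, hf_block = NULL)
  if (config$variant == "volumewise_hr") {
    out$hr_volume <- hr_volume_means(ibis, design)
  }
  if (config$variant == "hf_hrv") {
    wt <- hf_hrv(ibis, band = config$hf_band,
                 window_s = config$hf_window_s,
                 shift_s = config$hf_shift_s)
    out$hf_block <- window_block_means(wt, design)
  }
  out
}

# model regressors + contrast for one variant
variant_regressors <- function(variant, design, physio, hrf) {
  switch(variant,
    blockwise_hr = list(
      regs = list(build_task_regressor(design, hrf),
                  build_block_modulator(design, physio$hr_block, hrf)),
      contrast = c(0, 1)),
    volumewise_hr = list(
      regs = list(build_task_regressor(design, hrf),
                  build_volume_modulator(design, physio$hr_volume, hrf)),
      contrast = c(0, 1)),
    hf_hrv = list(
      regs = list(build_task_regressor(design, hrf),
                  build_block_modulator(design, physio$hf_block, hrf,
                                        name = "hf_block")),
      contrast = c(0, 1)),
    phasewise_hr = list(
      regs = build_phasewise_regressors(design, physio$hr_block, hrf),
      contrast = c(0, 0, 0, 1, 1, 1) / 3),
    task_only = list(
      regs = build_phasewise_regressors(design, NULL, hrf),
      contrast = c(-1, 2, -1)),
    stop("unknown variant ", variant))
}

#' Run the first-level analysis for one subject
#'
#' Quality control (mean framewise displacement, PPG quality rating),
#' physiological trace extraction, stage-one nuisance residualization
#' (motion, differential motion, DVARS spikes, linear trend), CompCor,
#' smoothing, GLM fit of the configured model variant and its modulator
#' (or task) contrast. Subjects failing QC are returned as excluded
#' records with a machine-readable reason; the run continues.
#'
#' @param subject A [simulate_subject()]-style list: \code{ppg},
#'   \code{vol}, \code{masks} (brain, wm, csf), \code{motion}.
#' @param design A \code{task_design}.
#' @param config A [run_config()].
#' @param variants For \code{run_subject_variants}, a character vector of
#'   model variants to fit on the shared preprocessed volume.
#' @return A list: \code{included}, \code{reason} (\code{NA} when
#'   included), \code{contrast} (\code{contrast_map}; for
#'   \code{run_subject_variants} a named list \code{contrasts}),
#'   \code{physio}, \code{qc} (fd summary), \code{design_matrix}.
#' @export
run_subject <- function(subject, design, config = run_config()) {
  rec <- run_subject_variants(subject, design, config, config$variant)
  rec$contrast <- rec$contrasts[[config$variant]]
  rec
}

#' @rdname run_subject
#' @export
run_subject_variants <- function(subject, design, config = run_config(),
                                 variants = config$variant) {
  rec <- list(id = subject$id, included = FALSE, reason = NA_character_)
  if (!is.null(subject$motion)) {
    fd <- framewise_displacement(subject$motion,
                                 radius = config$fd_radius_mm,
                                 exclude_mm = config$fd_limit_mm)
    rec$qc <- list(mean_fd = fd$mean_fd)
    if (fd$excluded) {
      rec$reason <- "motion"
      return(rec)
    }
  }
  need_vol <- "volumewise_hr" %in% variants
  need_hf <- "hf_hrv" %in% variants
  pconf <- config
  pconf$variant <- if (need_hf) "hf_hrv" else if (need_vol)
    "volumewise_hr" else variants[1]
  physio <- subject_physio(subject$ppg, design, pconf)
  if (!is.null(physio$ibis) && need_vol && is.null(physio$hr_volume)) {
    physio$hr_volume <- hr_volume_means(physio$ibis, design)
  }
  rec$physio <- physio
  if (is.null(physio$ibis)) {
    rec$reason <- "physio_quality"
    return(rec)
  }
  traces <- list(physio$hr_block)
  if (need_hf) traces <- c(traces, list(physio$hf_block))
  if (any(variants != "task_only") &&
      any(vapply(traces, function(tr) anyNA(trace_values(tr)), TRUE))) {
    rec$reason <- "physio_missing_block"
    return(rec)
  }
  if (is.null(subject$vol)) {
    rec$included <- TRUE
    return(rec)
  }
  reg_design <- design
  extra_regs <- list()
  if (!is.null(config$onset_control_s)) {
    extra_regs <- list(build_onset_control(design, config$onset_control_s,
                                           config$hrf))
    reg_design <- trim_active_onsets(design, config$onset_control_s)
  }
  vol <- subject$vol
  spikes <- NULL
  if (config$residualize) {
    dv <- dvars(vol, subject$masks$brain)
    spikes <- dv$spikes
    vol <- residualize(vol, subject$motion, spikes,
                       mask = subject$masks$brain)
  }
  cc <- if (config$compcor_per_tissue) {
    cbind(compcor(vol, subject$masks$wm, config$n_compcor),
          compcor(vol, subject$masks$csf, config$n_compcor))
  } else {
    comb <- mask3d(subject$masks$wm$mask | subject$masks$csf$mask,
                   subject$masks$wm$affine)
    compcor(vol, comb, config$n_compcor)
  }
  if (config$compcor_per_tissue) {
    colnames(cc) <- paste0("compcor_", seq_len(ncol(cc)))
  }
  if (config$smooth) vol <- smooth_gaussian(vol, config$fwhm_mm)
  drift <- dct_highpass_basis(n_scans(design), design_tr(design),
                              config$highpass_s)
  rec$contrasts <- list()
  for (v in variants) {
    vr <- variant_regressors(v, reg_design, physio, config$hrf)
    X <- assemble_design(c(vr$regs, extra_regs, drift),
                         nuisance = build_nuisance_set(compcor = cc),
                         tr = design_tr(design))
    fit <- fit_glm(vol, X, subject$masks$brain)
    rec$contrasts[[v]] <- t_contrast(fit, vr$contrast)
    rec$design_matrix <- X$meta
  }
  rec$included <- TRUE
  rec
}

#' Group-level analysis over first-level results
#'
#' One-sample t-tests of the forwarded contrast in both directions with
#' Bonferroni voxel-level FWE and cluster extent filtering. Excluded
#' subjects are reported, never silently dropped.
#'
#' @param results List of [run_subject()] records.
#' @param mask Group analysis [mask3d()] (e.g. the brain mask).
#' @param config A [run_config()].
#' @return A list: \code{positive} / \code{negative} (thresholded
#'   \code{group_result}s with \code{clusters}), \code{n_included},
#'   \code{exclusions} (data frame id/reason).
#' @export
run_group <- function(results, mask, config = run_config()) {
  inc <- Filter(function(r) isTRUE(r$included) && !is.null(r$contrast),
                results)
  exc <- Filter(function(r) !isTRUE(r$included), results)
  if (length(inc) < 3) {
    stop("only ", length(inc), " included subjects; need at least 3")
  }
  maps <- lapply(inc, `[[`, "contrast")
  out <- list()
  for (dir in c(1, -1)) {
    g <- one_sample_t(maps, mask, direction = dir)
    g <- fwe_voxel_threshold(g, alpha = config$alpha)
    cl <- clusterize(g, extent_k = config$extent_k,
                     connectivity = config$connectivity)
    g$clusters <- cl$clusters
    g$cluster_labels <- cl$labels
    out[[if (dir > 0) "positive" else "negative"]] <- g
  }
  out$n_included <- length(inc)
  out$exclusions <- data.frame(
    id = vapply(exc, function(r) as.integer(r$id), 0L),
    reason = vapply(exc, function(r) r$reason, ""))
  out
}

#' Effect-size table comparing model variants on ROI betas
#'
#' Cohen's D (pooled-SD units) of the main variant's mean ROI modulator
#' betas against each control variant, per ROI, with paired-test
#' p-values — the package's analogue of an effect-size comparison table.
#'
#' @param maps_by_variant Named list: for each variant, a list of
#'   per-subject \code{contrast_map}s (same subjects, same order).
#' @param rois Named list of [mask3d()] ROIs.
#' @param main Name of the main variant (default \code{"blockwise_hr"}).
#' @return A data frame of [cohens_d_models()] rows.
#' @export
effect_size_table <- function(maps_by_variant, rois,
                              main = "blockwise_hr") {
  stopifnot(main %in% names(maps_by_variant))
  controls <- setdiff(names(maps_by_variant), main)
  rows <- list()
  for (rn in names(rois)) {
    a <- extract_roi_betas(maps_by_variant[[main]], rois[[rn]])
    for (ctrl in controls) {
      b <- extract_roi_betas(maps_by_variant[[ctrl]], rois[[rn]])
      rows[[length(rows) + 1L]] <-
        cohens_d_models(a, b, roi = rn, model_a = main, model_b = ctrl)
    }
  }
  do.call(rbind, rows)
}
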