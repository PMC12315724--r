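#' Read and write volumes and masks as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. Affines map 0-based voxel indices to
#' mm (RAS+).
#'
#' @param vol A [volume4d()] (or [mask3d()] for \code{write_mask}).
#' @param path Destination (.nii or .nii.gz).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param tr Repetition time to attach (s).
#' @export
read_volume <- function(path, tr = 2) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  volume4d(array(as.numeric(img), dim(img)), unclass(aff), tr)
}

#' @rdname write_volume
#' @export
write_mask <- function(vol, path) {
  img <- RNifti::asNifti(array(as.numeric(vol$mask), dim(vol$mask)))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param threshold Probability threshold for binarizing (e.g. 0.99 for
#'   white matter, 0.95 for CSF tissue-probability maps).
#' @export
read_mask <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  mask3d(array(as.numeric(img) > threshold, dim(img)), unclass(aff))
}

#' Read / write physiological recordings (BIDS physio convention)
#'
#' A gzipped single-column TSV of samples plus a JSON sidecar with
#' \code{SamplingFrequency}, \code{StartTime} and \code{Columns}.
#'
#' @param rec A [physio_recording()].
#' @param path Path to the \code{.tsv.gz} file; the sidecar replaces the
#'   extension with \code{.json}.
#' @export
write_physio <- function(rec, path) {
  con <- gzfile(path, "wb")
  writeLines(format(rec$samples, trim = TRUE, digits = 10), con)
  close(con)
  side <- sub("\\.tsv\\.gz$", ".json", path)
  jsonlite::write_json(list(SamplingFrequency = rec$fs,
                            StartTime = rec$start_offset,
                            Columns = list(rec$channel)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_physio
#' @export
read_physio <- function(path) {
  side <- sub("\\.tsv\\.gz$", ".json", path)
  meta <- jsonlite::read_json(side)
  con <- gzfile(path, "rb")
  x <- as.numeric(readLines(con))
  close(con)
  physio_recording(x, meta$SamplingFrequency, meta$StartTime,
                   unlist(meta$Columns)[1])
}

#' Export a design matrix as TSV plus JSON sidecar
#'
#' @param X A \code{design_matrix}.
#' @param path Path to the TSV; the sidecar (column kinds, tr) replaces
#'   the extension with \code{.json}.
#' @export
write_design_tsv <- function(X, path) {
  df <- as.data.frame(X$X)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(tr = X$tr, rank = X$rank,
                            columns = X$meta),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a simulated cohort as a BIDS-like directory tree
#'
#' Per subject: events, physio (TSV.GZ + JSON), motion TSV and, when
#' rendered, the BOLD NIfTI with mask volumes under
#' \code{derivatives/truth}. Ratings and a JSON manifest with all
#' ground-truth parameters and per-subject seeds sit at the root.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param out_dir Destination directory.
#' @param force Overwrite a non-empty directory.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force) {
    stop("output directory ", out_dir,
         " exists and is not empty (use force = TRUE)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(cohort$design, file.path(out_dir, "task_events.tsv"))
  write.table(cbind(subject = seq_len(nrow(cohort$ratings)),
                    cohort$ratings),
              file.path(out_dir, "ratings.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    sd <- file.path(out_dir, sprintf("sub-%02d", i), "func")
    dir.create(sd, recursive = TRUE, showWarnings = FALSE)
    write_physio(s$ppg, file.path(sd, sprintf(
      "sub-%02d_task-stress_physio.tsv.gz", i)))
    if (!is.null(s$motion)) {
      write.table(s$motion, file.path(sd, sprintf(
        "sub-%02d_task-stress_motion.tsv", i)),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
    if (!is.null(s$vol)) {
      write_volume(s$vol, file.path(sd, sprintf(
        "sub-%02d_task-stress_bold.nii.gz", i)))
      td <- file.path(out_dir, "derivatives", "truth", sprintf("sub-%02d", i))
      dir.create(td, recursive = TRUE, showWarnings = FALSE)
      for (mn in names(s$masks)) {
        write_mask(s$masks[[mn]], file.path(td, paste0(mn, ".nii.gz")))
      }
    }
  }
  manifest <- list(config = unclass(cohort$config),
                   master_seed = cohort$truth$master_seed,
                   seeds = cohort$truth$seeds,
                   low_quality = cohort$truth$low_quality,
                   upswing = cohort$truth$upswing)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
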