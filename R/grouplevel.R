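#' Random-effects one-sample t-test over subjects
#'
#' Voxelwise one-sample t-test of per-subject contrast effects against
#' zero, one-sided in the requested direction (\code{+1}: mean > 0,
#' \code{-1}: mean < 0). Voxels with zero across-subject variance are
#' flagged and excluded from thresholding with a warning.
#'
#' @param maps List of per-subject \code{contrast_map}s (or bare 3D effect
#'   arrays on a common grid).
#' @param mask A [mask3d()] restricting the test.
#' @param direction \code{+1} or \code{-1}.
#' @return A \code{group_result}: 3D \code{t} and one-sided \code{p}
#'   arrays, \code{df = N - 1}, \code{n}, \code{direction}, affine.
#' @export
one_sample_t <- function(maps, mask, direction = 1) {
  stopifnot(length(maps) >= 3, direction %in% c(1, -1))
  affine <- if (inherits(maps[[1]], "contrast_map")) maps[[1]]$affine
            else diag(4)
  eff <- vapply(maps, function(m) {
    a <- if (inherits(m, "contrast_map")) m$effect else m
    a[mask$mask]
  }, numeric(sum(mask$mask)))                 # voxels x subjects
  n <- ncol(eff)
  mu <- rowMeans(eff)
  s <- sqrt(rowSums((eff - mu)^2) / (n - 1))
  zero_var <- s < 1e-12
  if (any(zero_var)) {
    warning(sum(zero_var), " voxel(s) with zero across-subject variance",
            " excluded from thresholding")
  }
  tval <- ifelse(zero_var, NA_real_, mu / (s / sqrt(n)))
  df <- n - 1
  p <- if (direction > 0) pt(tval, df, lower.tail = FALSE) else pt(tval, df)
  to_arr <- function(v) {
    a <- array(NA_real_, dim(mask$mask))
    a[mask$mask] <- v
    a
  }
  structure(list(t = to_arr(tval), p = to_arr(p), df = df, n = n,
                 direction = direction, mask = mask, affine = affine),
            class = "group_result")
}

#' Voxel-level family-wise-error thresholding
#'
#' Bonferroni correction over in-mask voxels: the per-voxel p threshold is
#' \code{alpha / V}. Conservative but assumption-free, in place of
#' random-field-theory correction.
#'
#' @param result A [one_sample_t()] result.
#' @param alpha Family-wise alpha (default 0.05).
#' @param method Only \code{"bonferroni"} is implemented.
#' @return The \code{group_result} augmented with \code{alpha},
#'   \code{p_threshold}, \code{n_tests} and a logical \code{supra} array.
#' @export
fwe_voxel_threshold <- function(result, alpha = 0.05,
                                method = c("bonferroni")) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  V <- sum(result$mask$mask)
  if (V == 0) stop("empty mask")
  thr <- alpha / V
  supra <- !is.na(result$p) & result$p < thr
  result$alpha <- alpha
  result$p_threshold <- thr
  result$n_tests <- V
  result$supra <- supra
  result
}

#' Uncorrected voxel thresholding (exploratory preset)
#'
#' @param result A [one_sample_t()] result.
#' @param p_uncorrected Uncorrected per-voxel p threshold (default 0.001).
#' @return As [fwe_voxel_threshold()], without correction.
#' @export
uncorrected_voxel_threshold <- function(result, p_uncorrected = 0.001) {
  stopifnot(p_uncorrected > 0, p_uncorrected < 1)
  result$alpha <- NA_real_
  result$p_threshold <- p_uncorrected
  result$n_tests <- sum(result$mask$mask)
  result$supra <- !is.na(result$p) & result$p < p_uncorrected
  result
}

# neighbour offsets for 6/18/26-connectivity
connectivity_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(off))
  lim <- switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3,
                stop("connectivity must be 6, 18 or 26"))
  off[nz >= 1 & nz <= lim, , drop = FALSE]
}

#' Connected-component clustering of suprathreshold voxels
#'
#' Labels connected components of the suprathreshold mask (18-connectivity
#' by default: face and edge neighbours), drops components smaller than
#' \code{extent_k} voxels, and reports each surviving cluster's size, peak
#' t, peak mm coordinates (via the affine) and Bonferroni-adjusted peak p.
#'
#' @param result A thresholded [fwe_voxel_threshold()] result.
#' @param extent_k Minimum cluster extent in voxels (default 25; the
#'   convention "clusters > 25 voxels" is read as \code{k >= extent_k}).
#' @param connectivity 6, 18 (default) or 26.
#' @return A list: \code{clusters} (data frame: label, k, peak_x/y/z mm,
#'   peak_t, peak_p_fwe) and \code{labels} (3D integer array, 0 =
#'   background).
#' @export
clusterize <- function(result, extent_k = 25, connectivity = 18) {
  stopifnot(extent_k >= 1, !is.null(result$supra))
  supra <- result$supra
  d <- dim(supra)
  off <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  comp <- 0L
  idx_all <- which(supra)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      co <- arrayInd(cur, d)
      nb <- sweep(off, 2, as.integer(co), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[supra[lin] & labels[lin] == 0L]
      labels[new] <- comp
      queue <- c(queue, new)
    }
  }
  rows <- list()
  out_labels <- array(0L, d)
  keep_id <- 0L
  V <- result$n_tests
  for (cid in seq_len(comp)) {
    vox <- which(labels == cid)
    k <- length(vox)
    if (k < extent_k) next
    keep_id <- keep_id + 1L
    out_labels[vox] <- keep_id
    tv <- result$t[vox]
    peak <- vox[which.max(if (result$direction > 0) tv else -tv)]
    co <- arrayInd(peak, d) - 1L               # 0-based voxel coords
    mm <- drop(result$affine %*% c(co, 1))[1:3]
    rows[[keep_id]] <- data.frame(
      label = keep_id, k = k,
      peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
      peak_t = result$t[peak],
      peak_p_fwe = min(1, result$p[peak] * V))
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), k = integer(0), peak_x = numeric(0),
               peak_y = numeric(0), peak_z = numeric(0),
               peak_t = numeric(0), peak_p_fwe = numeric(0))
  list(clusters = clusters, labels = out_labels)
}

#' Attach anatomical labels to clusters
#'
#' For each cluster, reports the fraction of its voxels falling in each
#' label of a user-supplied label volume (e.g. an anatomical atlas on the
#' same grid); labels covering at least \code{min_fraction} of the cluster
#' are kept. Without an atlas the clusters are returned unchanged
#' (coordinates-only rows).
#'
#' @param clust A [clusterize()] result.
#' @param atlas 3D integer label array on the same grid, or \code{NULL}.
#' @param atlas_names Optional named character vector mapping label values
#'   to region names.
#' @param min_fraction Minimum reported fraction of cluster voxels
#'   (default 0.05).
#' @return A data frame of cluster rows, one per (cluster, label) pair
#'   with columns \code{label}, \code{k}, \code{region}, \code{pct_k}
#'   merged with the peak statistics.
#' @export
label_clusters <- function(clust, atlas = NULL, atlas_names = NULL,
                           min_fraction = 0.05) {
  if (is.null(atlas)) return(clust$clusters)
  if (!identical(dim(atlas), dim(clust$labels))) {
    stop("atlas grid ", paste(dim(atlas), collapse = "x"),
         " does not match cluster grid ",
         paste(dim(clust$labels), collapse = "x"))
  }
  rows <- list()
  for (i in seq_len(nrow(clust$clusters))) {
    cid <- clust$clusters$label[i]
    vox <- which(clust$labels == cid)
    tab <- table(atlas[vox])
    frac <- as.numeric(tab) / length(vox)
    keep <- frac >= min_fraction
    vals <- names(tab)[keep]
    region <- if (!is.null(atlas_names)) {
      unname(ifelse(vals %in% names(atlas_names), atlas_names[vals], vals))
    } else vals
    rows[[i]] <- cbind(clust$clusters[rep(i, sum(keep)), , drop = FALSE],
                       region = region, pct_k = 100 * frac[keep])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
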