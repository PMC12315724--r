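#' 4D BOLD volume and 3D mask containers
#'
#' Thin containers around plain arrays: a \code{volume4d} holds an
#' x-y-z-t data grid, a 4x4 voxel-to-mm affine and the TR; a \code{mask3d}
#' holds a logical grid on the same lattice. Volumes are assumed already
#' motion-corrected and spatially normalized.
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param tr Repetition time (s).
#' @return A \code{volume4d} / \code{mask3d}.
#' @export
volume4d <- function(data, affine = diag(4), tr = 2) {
  stopifnot(length(dim(data)) == 4, nrow(affine) == 4, ncol(affine) == 4,
            abs(det(affine)) > 1e-12)
  structure(list(data = data, affine = affine, tr = tr), class = "volume4d")
}

#' @rdname volume4d
#' @param mask Logical (or 0/1 numeric) 3D array; must be non-empty.
#' @export
mask3d <- function(mask, affine = diag(4)) {
  mask <- array(as.logical(mask), dim(mask))
  stopifnot(length(dim(mask)) == 3, any(mask))
  structure(list(mask = mask, affine = affine), class = "mask3d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> %dx%dx%d voxels, %d scans, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

# in-mask timeseries as a scans x voxels matrix
mask_timeseries <- function(vol, mask) {
  d <- dim(vol$data)
  idx <- which(mask$mask)
  t(.gather_rows(vol$data, prod(d[1:3]), d[4], idx))
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: the sum of absolute frame-to-frame
#' changes of the three translations (mm) plus \code{radius} times those of
#' the three rotations (rad), approximating rotational displacement on a
#' sphere of \code{radius} mm. Subjects whose mean FD exceeds
#' \code{exclude_mm} are flagged for exclusion.
#'
#' @param motion Matrix or data frame with 6 columns: 3 translations (mm),
#'   3 rotations (rad).
#' @param radius Head radius for the rotation term (mm, default 50).
#' @param exclude_mm Mean-FD exclusion threshold (mm, default 1.5).
#' @return A list: \code{fd} (mm per scan, first scan 0), \code{mean_fd},
#'   \code{excluded} flag.
#' @export
framewise_displacement <- function(motion, radius = 50, exclude_mm = 1.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) {
    stop("motion must have 6 columns (3 translations, 3 rotations), got ",
         ncol(motion))
  }
  stopifnot(radius > 0)
  d <- abs(apply(motion, 2, function(col) c(0, diff(col))))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    radius * rowSums(d[, 4:6, drop = FALSE])
  list(fd = fd, mean_fd = mean(fd), excluded = mean(fd) > exclude_mm)
}

#' DVARS intensity-change series and spike flags
#'
#' Root-mean-square of the frame-to-frame intensity difference over
#' in-mask voxels, scaled by the median in-mask intensity. Scans whose
#' value exceeds the series median plus \code{spike_iqr} inter-quartile
#' ranges are flagged as spikes.
#'
#' @param vol A [volume4d()].
#' @param mask A [mask3d()] on the same grid.
#' @param spike_iqr Spike threshold in IQR units above the median.
#' @return A list: \code{dvars} (per scan, first 0), \code{spikes}
#'   (logical per scan).
#' @export
dvars <- function(vol, mask, spike_iqr = 1.5) {
  dd <- dim(vol$data)
  nv <- prod(dd[1:3])
  idx <- which(mask$mask)
  scan_sub <- as.integer(round(seq(1, dd[4], length.out = min(dd[4], 20))))
  med <- median(vol$data[as.vector(outer(idx, (scan_sub - 1) * nv, "+"))])
  if (abs(med) < 1e-12) med <- 1
  d <- .dvars_series(vol$data, nv, dd[4], idx) / abs(med)
  thr <- median(d) + spike_iqr * IQR(d)
  list(dvars = d, spikes = d > thr & d > 0)
}

#' Stage-one nuisance residualization
#'
#' Residualizes every voxel timeseries against a constant, a linear trend,
#' the six motion parameters, their first differences, and one-hot spike
#' regressors, then adds the voxel mean back (so percent-signal scaling
#' downstream is unaffected). Linearly dependent nuisance columns are
#' dropped with a warning.
#'
#' @param vol A [volume4d()].
#' @param motion 6-column motion matrix (may be \code{NULL}).
#' @param spikes Logical per-scan spike flags (may be \code{NULL}).
#' @param mask Optional [mask3d()]: only in-mask voxels are residualized
#'   (out-of-mask voxels pass through unchanged).
#' @return A residualized [volume4d()].
#' @export
residualize <- function(vol, motion = NULL, spikes = NULL, mask = NULL) {
  d <- dim(vol$data)
  n <- d[4]
  N <- cbind(constant = rep(1, n), trend = seq_len(n) - (n + 1) / 2)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    stopifnot(nrow(motion) == n)
    md <- apply(motion, 2, function(col) c(0, diff(col)))
    N <- cbind(N, motion, md)
  }
  if (!is.null(spikes) && any(spikes)) {
    oh <- vapply(which(spikes), function(i) {
      v <- numeric(n); v[i] <- 1; v
    }, numeric(n))
    N <- cbind(N, oh)
  }
  qrN <- qr(N)
  if (qrN$rank < ncol(N)) {
    warning("dropping ", ncol(N) - qrN$rank,
            " linearly dependent nuisance column(s)")
    N <- N[, qrN$pivot[seq_len(qrN$rank)], drop = FALSE]
    qrN <- qr(N)
  }
  nv <- prod(d[1:3])
  sel <- if (is.null(mask)) seq_len(nv) else which(mask$mask)
  Ym <- .gather_rows(vol$data, nv, n, sel)   # voxels x scans
  mu <- rowMeans(Ym)
  Q <- qr.Q(qrN)
  R <- Ym - (Ym %*% Q) %*% t(Q) + mu         # project out colspace(N)
  out <- .scatter_rows(vol$data, nv, sel, R)
  dim(out) <- d
  volume4d(out, vol$affine, vol$tr)
}

#' Anatomical CompCor nuisance components
#'
#' Principal components of the timeseries of voxels inside a noise-tissue
#' mask (white matter and/or CSF): each in-mask voxel series is centered
#' and variance-normalized, and the first \code{n_components} left singular
#' vectors of the scans-by-voxels matrix are returned as unit-norm columns.
#' Each component's sign is fixed so that it correlates positively with its
#' top-loading voxel.
#'
#' @param vol A [volume4d()] (residualized stage-one output).
#' @param mask A [mask3d()] of the noise compartment.
#' @param n_components Number of components (default 5).
#' @return A scans x \code{n_components} matrix, columns
#'   \code{compcor_1..k}.
#' @export
compcor <- function(vol, mask, n_components = 5) {
  Y <- mask_timeseries(vol, mask)           # scans x voxels
  if (ncol(Y) <= n_components) {
    stop("mask has ", ncol(Y), " voxels; need more than ", n_components)
  }
  Y <- sweep(Y, 2, colMeans(Y))
  s <- sqrt(colMeans(Y^2))
  keep <- s > 1e-12
  if (!any(keep)) stop("all in-mask voxels have zero variance")
  Y <- sweep(Y[, keep, drop = FALSE], 2, s[keep], "/")
  sv <- svd(Y, nu = n_components, nv = n_components)
  U <- sv$u
  for (k in seq_len(ncol(U))) {
    top <- which.max(abs(sv$v[, k]))
    if (sv$v[top, k] < 0) U[, k] <- -U[, k]
  }
  colnames(U) <- paste0("compcor_", seq_len(ncol(U)))
  U
}

#' Bundle nuisance columns for the first-level design
#'
#' @param compcor Matrix of CompCor columns (or \code{NULL}).
#' @param extra Additional named columns (or \code{NULL}).
#' @return A \code{nuisance_set}.
#' @export
build_nuisance_set <- function(compcor = NULL, extra = NULL) {
  structure(list(compcor = compcor, extra = extra), class = "nuisance_set")
}

nuisance_matrix <- function(ns) {
  parts <- Filter(Negate(is.null), list(ns$compcor, ns$extra))
  if (!length(parts)) return(NULL)
  do.call(cbind, parts)
}

# 1D Gaussian smoothing operator with mirror (whole-sample reflection)
# boundaries; symmetric, rows and columns sum to 1, so constants and the
# global mean are both preserved.
smooth_operator_1d <- function(d, sigma_vox) {
  if (sigma_vox <= 0 || d == 1) return(diag(d))
  r <- max(1L, ceiling(3 * sigma_vox))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  S <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- i + off
    # half-sample reflection: 0 -> 1, -1 -> 2, d+1 -> d, ...
    j <- ifelse(j < 1, 1 - j, j)
    j <- ifelse(j > d, 2 * d + 1 - j, j)
    j <- pmin(pmax(j, 1), d)
    for (m in seq_along(off)) S[i, j[m]] <- S[i, j[m]] + k[m]
  }
  S
}

#' Separable Gaussian spatial smoothing
#'
#' Smooths each scan with a separable Gaussian of the given full width at
#' half maximum per axis, converted to voxel units through the affine's
#' voxel sizes. Mirror boundary handling preserves both constant images
#' and the volume-wise mean.
#'
#' @param vol A [volume4d()].
#' @param fwhm FWHM in mm, scalar or length-3 (default 6 mm isotropic).
#' @return A smoothed [volume4d()].
#' @export
smooth_gaussian <- function(vol, fwhm = 6) {
  fwhm <- rep(fwhm, length.out = 3)
  stopifnot(all(fwhm >= 0))
  if (all(fwhm == 0)) return(vol)
  vox_mm <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / vox_mm
  d <- dim(vol$data)
  kern <- lapply(1:3, function(ax) {
    if (sigma_vox[ax] <= 0 || d[ax] == 1) return(1)
    r <- max(1L, ceiling(3 * sigma_vox[ax]))
    k <- exp(-((-r):r)^2 / (2 * sigma_vox[ax]^2))
    k / sum(k)
  })
  A <- .smooth3d(vol$data, d[1], d[2], d[3], d[4],
                 kern[[1]], kern[[2]], kern[[3]])
  dim(A) <- d
  volume4d(A, vol$affine, vol$tr)
}

#' Fit the mass-univariate GLM
#'
#' Ordinary least squares per in-mask voxel: beta solves the normal
#' equations, residual variance is \code{RSS / dof} with
#' \code{dof = n - rank(X)}. Refuses rank-deficient designs, naming the
#' dependent columns.
#'
#' @param vol A [volume4d()] (preprocessed).
#' @param X A \code{design_matrix} from [assemble_design()].
#' @param mask A [mask3d()]; voxels outside it are not fit.
#' @return A \code{glm_fit}: \code{beta} (columns x voxels), \code{sigma2},
#'   \code{dof}, \code{design}, \code{mask}, \code{xtx_inv}, plus grid
#'   geometry.
#' @export
fit_glm <- function(vol, X, mask) {
  stopifnot(inherits(X, "design_matrix"))
  M <- X$X
  n <- nrow(M)
  if (dim(vol$data)[4] != n) {
    stop("volume has ", dim(vol$data)[4], " scans but design has ", n)
  }
  qrX <- qr(M)
  if (qrX$rank < ncol(M)) {
    dep <- colnames(M)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design is rank deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  dd <- dim(vol$data)
  idx <- which(mask$mask)
  Yv <- .gather_rows(vol$data, prod(dd[1:3]), n, idx)  # voxels x scans
  xtx_inv <- chol2inv(chol(crossprod(M)))
  Bv <- (Yv %*% M) %*% xtx_inv              # voxels x p
  dof <- n - qrX$rank
  sigma2 <- rowSums((Yv - Bv %*% t(M))^2) / dof
  beta <- t(Bv)                             # p x voxels
  structure(list(beta = beta, sigma2 = sigma2, dof = dof, design = X,
                 mask = mask, xtx_inv = xtx_inv,
                 dim = dim(vol$data)[1:3], affine = vol$affine),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("<glm_fit> %d voxels, %d columns, dof %d\n",
              ncol(x$beta), nrow(x$beta), x$dof))
  invisible(x)
}

#' Linear contrast of a fitted GLM
#'
#' The effect is the contrast applied to the betas; its t-value divides
#' by the estimated standard error \code{sqrt(sigma2 * c (XtX)^-1 c)}.
#' A contrast shorter than the design is zero-padded on the right (the
#' nuisance/drift/constant columns sit at the end of the design).
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric contrast vector.
#' @return A \code{contrast_map}: 3D \code{effect} and \code{t} arrays
#'   (\code{NA} outside the mask), the padded contrast, \code{dof} and the
#'   affine.
#' @export
t_contrast <- function(fit, contrast) {
  p <- nrow(fit$beta)
  if (length(contrast) > p) stop("contrast longer than design")
  cvec <- c(contrast, numeric(p - length(contrast)))
  if (all(cvec == 0)) stop("contrast is all zero")
  eff <- drop(crossprod(cvec, fit$beta))
  se <- sqrt(fit$sigma2 * drop(crossprod(cvec, fit$xtx_inv %*% cvec)))
  tval <- ifelse(se > 0, eff / se, NA_real_)
  to_arr <- function(v) {
    a <- array(NA_real_, fit$dim)
    a[fit$mask$mask] <- v
    a
  }
  structure(list(effect = to_arr(eff), t = to_arr(tval), contrast = cvec,
                 dof = fit$dof, affine = fit$affine, mask = fit$mask),
            class = "contrast_map")
}
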