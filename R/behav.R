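#' Heart-rate up/downswing metrics
#'
#' Summarizes a subject's phase-level heart-rate dynamics:
#' \code{upswing} = mean HR over Stress active blocks minus mean over
#' PreStress active blocks; \code{downswing} = mean over Stress minus mean
#' over PostStress; \code{proportional_downswing} = downswing / upswing
#' (undefined, with a warning, when the upswing is below 0.1 bpm).
#'
#' @param trace A [block_trace()] with per-block phase labels covering the
#'   three phases.
#' @param design Optional \code{task_design} supplying phase labels when
#'   the trace has none.
#' @param phases Character vector naming the (pre, stress, post) phases.
#' @return A one-row data frame: \code{upswing}, \code{downswing},
#'   \code{proportional_downswing} (bpm, bpm, unitless).
#' @export
swing_metrics <- function(trace, design = NULL,
                          phases = c("PreStress", "Stress", "PostStress")) {
  v <- trace_values(trace)
  ph <- if (inherits(trace, "block_trace") && !is.null(trace$phase)) {
    trace$phase
  } else if (!is.null(design)) {
    active_blocks(design)$phase
  } else {
    stop("trace carries no phase labels and no design was supplied")
  }
  stopifnot(length(v) == length(ph), all(phases %in% ph))
  m <- vapply(phases, function(p) mean(v[ph == p], na.rm = TRUE), 0)
  up <- m[2] - m[1]
  down <- m[2] - m[3]
  prop <- if (abs(up) < 0.1) {
    warning("upswing below 0.1 bpm; proportional downswing undefined")
    NA_real_
  } else {
    down / up
  }
  data.frame(upswing = unname(up), downswing = unname(down),
             proportional_downswing = unname(prop))
}

#' Effective number of independent tests (Nyholt)
#'
#' Eigenvalue-based estimate of the effective number of independent tests
#' among correlated variables:
#' \code{meff = 1 + (M - 1) * (1 - var(lambda) / M)} over the eigenvalues
#' \code{lambda} of the correlation matrix. Equals \code{M} for
#' uncorrelated variables and 1 for perfectly correlated ones.
#'
#' @param R Correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite within tolerance).
#' @param tol Tolerance for symmetry / PSD checks.
#' @return The (unrounded) effective test count, in \code{[1, M]}.
#' @export
meff <- function(R, tol = 1e-8) {
  R <- as.matrix(R)
  M <- nrow(R)
  stopifnot(M == ncol(R))
  if (max(abs(R - t(R))) > tol) stop("matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > tol) stop("diagonal must be 1")
  lambda <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(lambda) < -tol * M) {
    stop("matrix is not positive semidefinite (min eigenvalue ",
         signif(min(lambda), 3), ")")
  }
  m <- 1 + (M - 1) * (1 - var(lambda) / M)
  min(max(m, 1), M)
}

#' Correlate heart-rate swing metrics with rating changes
#'
#' Pearson correlations between each swing metric and each pre-to-post
#' rating change, with significance judged against an alpha divided by
#' the effective number of tests ([meff()]) computed from the rating
#' variables' correlation matrix. Constant columns are skipped with a
#' warning.
#'
#' @param swings Data frame of per-subject swing metrics (e.g. from
#'   [swing_metrics()] rows).
#' @param deltas Data frame of per-subject rating changes (post minus
#'   pre), one column per scale/item.
#' @param alpha Family alpha before correction (default 0.05).
#' @param round_meff Round the effective test count to the nearest integer
#'   before dividing alpha? Default \code{FALSE} (unrounded).
#' @return A data frame of rows \code{swing}, \code{rating}, \code{r},
#'   \code{p}, \code{meff}, \code{adjusted_alpha}, \code{significant}.
#' @export
corr_with_ratings <- function(swings, deltas, alpha = 0.05,
                              round_meff = FALSE) {
  swings <- as.data.frame(swings)
  deltas <- as.data.frame(deltas)
  stopifnot(nrow(swings) == nrow(deltas))
  if (nrow(swings) < 10) stop("need at least 10 paired subjects, got ",
                              nrow(swings))
  keep_d <- vapply(deltas, function(x) stats::sd(x, na.rm = TRUE) > 1e-12,
                   TRUE)
  if (!all(keep_d)) {
    warning("skipping constant rating column(s): ",
            paste(names(deltas)[!keep_d], collapse = ", "))
    deltas <- deltas[, keep_d, drop = FALSE]
  }
  m <- meff(cor(deltas, use = "pairwise.complete.obs"))
  if (round_meff) m <- round(m)
  adj <- alpha / m
  rows <- list()
  for (sw in names(swings)) {
    if (stats::sd(swings[[sw]], na.rm = TRUE) < 1e-12) {
      warning("skipping constant swing column: ", sw)
      next
    }
    for (rt in names(deltas)) {
      ct <- cor.test(swings[[sw]], deltas[[rt]])
      rows[[length(rows) + 1L]] <- data.frame(
        swing = sw, rating = rt, r = unname(ct$estimate),
        p = ct$p.value, meff = m, adjusted_alpha = adj,
        significant = ct$p.value < adj)
    }
  }
  do.call(rbind, rows)
}
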