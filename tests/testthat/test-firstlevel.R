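test_that("framewise displacement follows the Power formula", {
  m0 <- matrix(0, 20, 6)
  fd0 <- framewise_displacement(m0)
  expect_true(all(fd0$fd == 0))
  expect_false(fd0$excluded)
  # single 1 mm translation step
  m1 <- m0; m1[10:20, 1] <- 1
  fd1 <- framewise_displacement(m1)
  expect_equal(fd1$fd[10], 1)
  expect_equal(sum(fd1$fd), 1)
  # 0.01 rad rotation step at 50 mm radius contributes 0.5 mm
  m2 <- m0; m2[5:20, 4] <- 0.01
  expect_equal(framewise_displacement(m2, radius = 50)$fd[5], 0.5)
  expect_error(framewise_displacement(m0[, 1:5]), "6 columns")
  # high sustained motion triggers the exclusion flag
  m3 <- apply(matrix(rnorm(20 * 6, 0, 2), 20, 6), 2, cumsum)
  expect_true(framewise_displacement(m3)$excluded)
})

test_that("dvars flags corrupted frames and is monotone in threshold", {
  v <- tiny_volume(n_scans = 60)
  v$data[] <- 100  # temporally constant
  msk <- full_mask()
  d0 <- dvars(v, msk)
  expect_true(all(d0$dvars == 0))
  expect_false(any(d0$spikes))
  # +10% on one frame -> one pair of elevated diffs, spike flagged
  set.seed(11)
  v2 <- tiny_volume(n_scans = 60)
  v2$data <- v2$data + 100
  v2$data[, , , 30] <- v2$data[, , , 30] * 1.1
  d2 <- dvars(v2, msk)
  expect_true(d2$spikes[30])
  expect_lte(sum(d2$spikes), 3)
  # spike count non-increasing in the threshold multiplier
  counts <- vapply(c(1, 1.5, 2.5, 4), function(k) {
    sum(dvars(v2, msk, spike_iqr = k)$spikes)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("residualization projects out nuisance structure only", {
  n <- 50
  set.seed(12)
  motion <- matrix(rnorm(n * 6, 0, 0.05), n, 6)
  dims <- c(4, 4, 4)
  arr <- array(0, c(dims, n))
  trend <- seq_len(n)
  # plant a signal orthogonal to the nuisance space (constant, trend,
  # motion, differential motion)
  md <- apply(motion, 2, function(col) c(0, diff(col)))
  N <- cbind(1, trend, motion, md)
  raw <- sin(2 * pi * seq_len(n) / 12)
  signal <- raw - N %*% qr.solve(N, raw)
  arr[1, 1, 1, ] <- 5 + 2 * trend           # pure linear trend
  arr[2, 1, 1, ] <- motion[, 1]             # copy of a motion parameter
  arr[3, 1, 1, ] <- signal                  # structure to preserve
  v <- volume4d(arr, diag(c(2, 2, 2, 1)), 2)
  rv <- residualize(v, motion)
  # trend voxel collapses to its mean
  expect_equal(rv$data[1, 1, 1, ], rep(mean(5 + 2 * trend), n),
               tolerance = 1e-8)
  # motion-copy voxel collapses to its mean (all motion removed)
  expect_lt(max(abs(rv$data[2, 1, 1, ] - mean(motion[, 1]))), 1e-10)
  # signal in the orthogonal complement is untouched
  expect_gt(cor(rv$data[3, 1, 1, ], signal), 0.999)
})

test_that("spike regressors zero the residual at spiked scans", {
  n <- 40
  set.seed(13)
  arr <- array(rnorm(4^3 * n), c(4, 4, 4, n))
  v <- volume4d(arr, diag(c(2, 2, 2, 1)), 2)
  spikes <- rep(FALSE, n); spikes[c(7, 21)] <- TRUE
  rv <- residualize(v, motion = NULL, spikes = spikes)
  mu <- apply(v$data, 1:3, mean)
  resid_at_spike <- rv$data[, , , 7] - mu
  expect_lt(max(abs(resid_at_spike)), 1e-8)
})

test_that("CompCor recovers planted noise components", {
  n <- 120
  set.seed(14)
  dims <- c(5, 5, 5)
  sinus <- sin(2 * pi * seq_len(n) / 16)
  arr <- array(rnorm(prod(dims) * n, 0, 1), c(dims, n))
  msk <- array(FALSE, dims); msk[2:4, 2:4, 2] <- TRUE
  for (i in which(msk)) {
    co <- arrayInd(i, dims)
    arr[co[1], co[2], co[3], ] <- arr[co[1], co[2], co[3], ] + 3 * sinus
  }
  v <- volume4d(arr, diag(c(2, 2, 2, 1)), 2)
  cc <- compcor(v, mask3d(msk, v$affine), 5)
  expect_equal(ncol(cc), 5)
  expect_gt(abs(cor(cc[, 1], sinus)), 0.95)
  G <- crossprod(cc)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)  # mutually orthogonal
  expect_error(compcor(v, mask3d(msk, v$affine), 10), "voxels")
})

test_that("Gaussian smoothing has the right width and conserves structure", {
  dims <- c(21, 21, 21)
  arr <- array(0, c(dims, 1)); arr[11, 11, 11, 1] <- 1
  v <- volume4d(arr, diag(c(2, 2, 2, 1)), 2)
  sm <- smooth_gaussian(v, 6)
  prof <- sm$data[, 11, 11, 1]
  # Gaussian width: fit sigma from log-profile; fwhm 6 mm at 2 mm voxels
  off <- 1:3
  lr <- log(prof[11] / prof[11 + off])
  sig_hat <- sqrt(mean(off^2 / (2 * lr)))
  expect_equal(sig_hat * 2 * sqrt(2 * log(2)) * 2, 6, tolerance = 0.02)
  # half maximum reached 3 mm (1.5 voxels) from the peak
  expect_gt(prof[12], 0.5 * prof[11])
  expect_lt(prof[13], 0.5 * prof[11])
  # mass, mean, constants
  expect_equal(sum(sm$data), 1, tolerance = 1e-10)
  expect_identical(smooth_gaussian(v, 0), v)
  cv <- volume4d(array(7, c(8, 8, 8, 2)), diag(c(2, 2, 2, 1)), 2)
  expect_equal(smooth_gaussian(cv, 6)$data, cv$data, tolerance = 1e-12)
  # global mean conserved on arbitrary data
  rv <- tiny_volume(n_scans = 5)
  expect_equal(mean(smooth_gaussian(rv, 6)$data), mean(rv$data),
               tolerance = 1e-12)
})

test_that("GLM fits match the closed-form oracle on random designs", {
  set.seed(15)
  for (rep in 1:50) {
    n <- 20; p <- 4
    X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
    colnames(X) <- c("constant", paste0("x", 1:(p - 1)))
    y <- rnorm(n)
    dm <- structure(list(X = X,
                         meta = data.frame(name = colnames(X),
                                           kind = c("constant", "task",
                                                    "task", "task")),
                         tr = 2, rank = qr(X)$rank),
                    class = "design_matrix")
    arr <- array(0, c(1, 1, 1, n)); arr[1, 1, 1, ] <- y
    v <- volume4d(arr, diag(4), 2)
    fit <- fit_glm(v, dm, mask3d(array(TRUE, c(1, 1, 1)), diag(4)))
    # independent oracle: normal equations via solve()
    beta_ref <- solve(t(X) %*% X, t(X) %*% y)
    expect_lt(max(abs(fit$beta[, 1] - beta_ref)), 1e-8)
    res <- y - X %*% beta_ref
    expect_equal(fit$sigma2[1], sum(res^2) / (n - p), tolerance = 1e-8)
  }
})

test_that("noiseless data are interpolated exactly", {
  n <- 30
  x <- sin(seq_len(n))
  X <- cbind(constant = 1, task = x)
  dm <- structure(list(X = X,
                       meta = data.frame(name = colnames(X),
                                         kind = c("constant", "task")),
                       tr = 2, rank = 2), class = "design_matrix")
  arr <- array(0, c(1, 1, 1, n)); arr[1, 1, 1, ] <- 2 + 3 * x
  fit <- fit_glm(volume4d(arr, diag(4), 2), dm,
                 mask3d(array(TRUE, c(1, 1, 1)), diag(4)))
  expect_equal(unname(fit$beta[, 1]), c(2, 3), tolerance = 1e-10)
  expect_equal(fit$sigma2[1], 0, tolerance = 1e-12)
})

test_that("rank-deficient designs are refused with the offending column", {
  n <- 20
  X <- cbind(constant = 1, a = rnorm(n))
  X <- cbind(X, b = X[, "a"])
  dm <- structure(list(X = X,
                       meta = data.frame(name = colnames(X),
                                         kind = c("constant", "task",
                                                  "task")),
                       tr = 2, rank = 2), class = "design_matrix")
  arr <- array(rnorm(n), c(1, 1, 1, n))
  expect_error(fit_glm(volume4d(arr, diag(4), 2), dm,
                       mask3d(array(TRUE, c(1, 1, 1)), diag(4))),
               "rank deficient")
})

test_that("t-contrasts match lm() and are sign-symmetric", {
  set.seed(16)
  n <- 25
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n, 0, 0.5)
  X <- cbind(task = x, constant = 1)
  dm <- structure(list(X = X,
                       meta = data.frame(name = colnames(X),
                                         kind = c("task", "constant")),
                       tr = 2, rank = 2), class = "design_matrix")
  arr <- array(0, c(1, 1, 1, n)); arr[1, 1, 1, ] <- y
  fit <- fit_glm(volume4d(arr, diag(4), 2), dm,
                 mask3d(array(TRUE, c(1, 1, 1)), diag(4)))
  cm_pos <- t_contrast(fit, c(1, 0))
  cm_neg <- t_contrast(fit, c(-1, 0))
  ref <- summary(lm(y ~ x))$coefficients["x", ]
  expect_equal(cm_pos$effect[1, 1, 1], unname(ref["Estimate"]),
               tolerance = 1e-10)
  expect_equal(cm_pos$t[1, 1, 1], unname(ref["t value"]), tolerance = 1e-10)
  expect_equal(cm_neg$t[1, 1, 1], -cm_pos$t[1, 1, 1])
  expect_error(t_contrast(fit, c(0, 0)), "zero")
  # short contrasts are right-padded over trailing columns
  expect_equal(t_contrast(fit, 1)$t[1, 1, 1], cm_pos$t[1, 1, 1])
})

test_that("two-stage residualization agrees with the joint model
          (Frisch-Waugh)", {
  set.seed(17)
  n <- 60
  motion <- matrix(rnorm(n * 6, 0, 0.1), n, 6)
  task <- rep(c(0, 1), each = 10, length.out = n)
  y <- 2 + 0.5 * task + motion %*% rnorm(6) + rnorm(n, 0, 0.2)
  # joint model: task + constant + trend + motion + motion_diff
  md <- apply(motion, 2, function(col) c(0, diff(col)))
  N <- cbind(1, seq_len(n) - (n + 1) / 2, motion, md)
  Xj <- cbind(task, N)
  bj <- qr.solve(Xj, y)
  # two-stage: residualize y AND the task regressor against N, then fit
  arr <- array(0, c(1, 1, 1, n)); arr[1, 1, 1, ] <- y
  rv <- residualize(volume4d(arr, diag(4), 2), motion)
  P <- N %*% solve(crossprod(N)) %*% t(N)
  task_r <- task - P %*% task
  yr <- rv$data[1, 1, 1, ] - mean(rv$data[1, 1, 1, ])
  b2 <- sum(task_r * yr) / sum(task_r^2)
  expect_equal(b2, unname(bj[1]), tolerance = 1e-6)
})
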