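test_that("default paradigm timing matches the acquisition protocol", {
  d <- build_task_design()
  expect_equal(sum(d$kind == "active"), 15)
  expect_equal(n_scans(d), 750)
  expect_equal(n_scans(d) + attr(d, "n_dummy"), 755)
  expect_equal(max(d$onset + d$duration), 1500)  # 25 min
  # every active block is followed by a rest block
  expect_true(all(d$kind[seq(1, nrow(d), 2)] == "active"))
  expect_true(all(d$kind[seq(2, nrow(d), 2)] == "rest"))
  # blocks non-overlapping and ordered
  expect_true(all(diff(d$onset) > 0))
  expect_true(all(d$onset[-1] >= (d$onset + d$duration)[-nrow(d)] - 1e-12))
})

test_that("single-block and invalid designs behave as specified", {
  d1 <- build_task_design(1, 1, 60, 40, 2, 0)
  expect_equal(sum(d1$kind == "active"), 1)
  expect_equal(d1$onset[d1$kind == "active"], 0)
  expect_equal(n_scans(d1), 50)
  expect_error(build_task_design(1, 1, 60, 40, 7), "remainder")
})

test_that("canonical double-gamma HRF has the expected shape", {
  k <- canonical_hrf(hrf_params(), dt = 0.1)
  expect_equal((which.max(k) - 1) * 0.1, 5, tolerance = 0.02)  # mode 5 s
  expect_equal(max(k), 1)
  # exactly one sign change: positive lobe then undershoot
  s <- sign(k[abs(k) > 1e-12])
  expect_equal(sum(diff(s) != 0), 1)
  # undershoot vanishes as the amplitude ratio grows
  k_inf <- canonical_hrf(hrf_params(ratio = 1e9), dt = 0.1)
  expect_true(all(k_inf >= -1e-12))
})

test_that("task regressor is a sampled HRF-convolved boxcar", {
  d <- tiny_design()
  r <- build_task_regressor(d)
  expect_equal(length(r$values), n_scans(d))
  expect_equal(r$kind, "task")
  # plateau positive during (delayed) active support, decays during rest
  expect_true(all(r$values[6:10] > 0.5 * max(r$values)))
  # no active blocks -> all-zero regressor
  d0 <- d
  d0$kind[d0$kind == "active"] <- "rest"
  expect_true(all(build_task_regressor(d0)$values == 0))
})

test_that("task regressor matches a direct convolution oracle", {
  d <- tiny_design()
  hp <- hrf_params()
  r <- build_task_regressor(d, hp)
  # independent oracle: brute-force discrete convolution at microtime
  mt <- hp$microtime_bins
  dt <- design_tr(d) / mt
  nm <- n_scans(d) * mt
  tt <- (seq_len(nm) - 1) * dt
  box <- numeric(nm)
  act <- d[d$kind == "active", ]
  for (j in seq_len(nrow(act))) {
    box[tt >= act$onset[j] & tt < act$onset[j] + act$duration[j]] <- 1
  }
  k <- canonical_hrf(hp, dt)
  conv <- numeric(nm)
  for (i in seq_len(nm)) {
    m <- seq_len(min(i, length(k)))
    conv[i] <- sum(k[m] * box[i - m + 1])
  }
  expect_equal(r$values, conv[seq(1, nm, by = mt)], tolerance = 1e-10)
})

test_that("blockwise modulator is mean-centered and convolution-linear", {
  d <- tiny_design()
  n_act <- sum(d$kind == "active")
  # constant trace annihilated by centering
  expect_true(all(build_block_modulator(d, rep(75, n_act))$values == 0))
  expect_error(build_block_modulator(d, rep(75, n_act + 1)), "active")
  # two-block toy: centering gives (-10, +10); modulator equals the
  # difference of the two per-block convolved boxcars times 10
  d2 <- build_task_design(1, 2, 20, 20, 2, 0)
  m <- build_block_modulator(d2, c(60, 80))
  per_block <- build_phasewise_regressors(d2)  # one phase
  b1 <- single_block_regressor(d2, 1)
  b2 <- single_block_regressor(d2, 2)
  expect_equal(m$values, 10 * (b2$values - b1$values), tolerance = 1e-10)
})

test_that("phasewise task regressors sum to the all-phase regressor", {
  d <- default_design()
  single <- build_task_regressor(d)
  per_phase <- build_phasewise_regressors(d)
  expect_length(per_phase, 3)
  summed <- Reduce(`+`, lapply(per_phase, `[[`, "values"))
  expect_lt(max(abs(summed - single$values)), 1e-10)
  # constant trace -> zero modulators, and the Stress-vs-rest contrast
  # spans the three phase columns
  regs <- build_phasewise_regressors(d, rep(70, 15))
  expect_length(regs, 6)
  mods <- regs[4:6]
  expect_true(all(vapply(mods, function(r) all(r$values == 0), TRUE)))
})

test_that("volumewise modulator agrees with blockwise on constant blocks", {
  d <- default_design()
  act <- scan_is_active(d)
  set.seed(7)
  block_vals <- rnorm(15, 75, 4)
  # per-scan trace constant within blocks
  scan_trace <- numeric(n_scans(d))
  blk <- scan_block_index(d)
  scan_trace[act] <- block_vals[blk[act]]
  scan_trace[!act] <- 75
  mv <- build_volume_modulator(d, scan_trace)
  mb <- build_block_modulator(d, block_vals)
  expect_lt(max(abs(mv$values - mb$values)), 1e-8)
  # constant trace -> zero; rest-scan values never contribute
  expect_true(all(build_volume_modulator(d, rep(70, 750))$values == 0))
  tr2 <- rep(70, 750)
  tr2[which(!act)[3]] <- 200
  expect_true(all(build_volume_modulator(d, tr2)$values == 0))
})

test_that("onset-control regressor covers only each block's head", {
  d <- default_design()
  ctrl <- build_onset_control(d, 10)
  expect_equal(ctrl$kind, "control")
  # pre-convolution support: 15 blocks x 10 s; check via near-delta HRF
  hp <- hrf_params(peak_delay = 0.05, peak_disp = 0.01, ratio = 1e9,
                   undershoot_delay = 1, undershoot_disp = 0.01,
                   length_s = 1)
  c10 <- build_onset_control(d, 10, hp)
  c20 <- build_onset_control(d, 20, hp)
  expect_equal(sum(c10$values > 0.5 * max(c10$values)) * design_tr(d), 150)
  expect_equal(sum(c20$values > 0.5 * max(c20$values)) * design_tr(d), 300)
  expect_error(build_onset_control(d, 0), "head_s")
  expect_error(build_onset_control(d, 60), "head_s")
  # trimmed design rebuilds the task boxcar over the remainder
  dtrim <- trim_active_onsets(d, 10)
  expect_equal(active_total_duration(dtrim), 15 * 50)
})

test_that("DCT high-pass basis has the documented column count and is
          orthonormal", {
  dct <- dct_highpass_basis(750, 2, 256)
  expect_length(dct, 11)  # floor(2 * 1500 / 256)
  expect_length(dct_highpass_basis(100, 1, 1000), 0)
  X <- vapply(dct, `[[`, numeric(750), "values")
  G <- crossprod(X)
  expect_lt(max(abs(G - diag(11))), 1e-10)
  expect_error(dct_highpass_basis(100, 2, 3), "cutoff")
})

test_that("assemble_design orders, checks and counts columns", {
  d <- default_design()
  task <- build_task_regressor(d)
  mod <- build_block_modulator(d, rnorm(15, 75, 3))
  dct <- dct_highpass_basis(750, 2, 256)
  cc <- matrix(rnorm(750 * 5), 750, 5,
               dimnames = list(NULL, paste0("compcor_", 1:5)))
  X <- assemble_design(c(list(task, mod), dct),
                       nuisance = build_nuisance_set(compcor = cc), tr = 2)
  expect_equal(ncol(X$X), 19)  # 1 task + 1 mod + 5 PCs + 11 DCT + const
  expect_equal(X$meta$kind,
               c("task", "modulator", rep("nuisance", 5),
                 rep("drift", 11), "constant"))
  expect_equal(X$rank, 19)
  expect_equal(sum(X$meta$kind == "constant"), 1)
  expect_error(assemble_design(list()), "no regressors")
  expect_error(assemble_design(list(task, task)), "duplicate")
  # duplicated (renamed) column lowers rank but still assembles
  task2 <- task
  task2$name <- "task_copy"
  X2 <- assemble_design(list(task, task2))
  expect_lt(X2$rank, ncol(X2$X))
})

test_that("events TSV round-trips the design", {
  d <- default_design()
  f <- file.path(tempdir(), "events.tsv")
  write_events_tsv(d, f)
  d2 <- read_events_tsv(f, tr = 2, n_dummy = 5)
  expect_equal(d2$onset, d$onset)
  expect_equal(d2$kind, d$kind)
  expect_equal(n_scans(d2), 750)
})
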