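test_that("resampling preserves duration, identity and sinusoid amplitude", {
  set.seed(1)
  rec <- physio_recording(rnorm(50000), 5000)
  out <- resample_physio(rec, 100)
  expect_equal(length(out$samples), 1000)  # 10 s at 100 Hz
  expect_equal(out$fs, 100)
  expect_identical(resample_physio(rec, 5000)$samples, rec$samples)
  # 1 Hz sinusoid survives 5000 -> 100 Hz with < 1% amplitude loss
  t5k <- (0:49999) / 5000
  sine <- physio_recording(sin(2 * pi * 1 * t5k), 5000)
  ds <- resample_physio(sine, 100)
  t100 <- (seq_along(ds$samples) - 1) / 100
  interior <- t100 > 1 & t100 < 9  # away from window edges
  amp_err <- max(abs(ds$samples[interior] - sin(2 * pi * t100[interior])))
  expect_lt(amp_err, 0.01)
})

test_that("beat detection recovers a clean pulse train and rates quality", {
  set.seed(2)
  bt <- constant_beats(60, 300)
  ppg <- render_ppg(bt, fs = 100, snr_db = 20, seed = 3, duration_s = 300)
  det <- detect_beats(ppg)
  expect_lte(det$quality$rating, 2)
  ib <- diff(det$beats$beat_times)
  # every detected interval within one sample of the true 1 s spacing
  expect_lt(max(abs(ib - 1)), 0.02 + 1e-9)
  expect_equal(length(det$beats$beat_times), length(bt))
  # flat zero trace: no beats, unusable rating
  flat <- physio_recording(rep(0, 30000), 100)
  det0 <- detect_beats(flat)
  expect_length(det0$beats$beat_times, 0)
  expect_equal(det0$quality$rating, 3L)
})

test_that("a sensor dropout is reflected in the longest-gap statistic", {
  set.seed(4)
  bt <- constant_beats(60, 300)
  ppg <- render_ppg(bt, fs = 100, snr_db = 20, seed = 5, duration_s = 300,
                    dropout_s = c(100, 110))
  det <- detect_beats(ppg)
  expect_gt(det$quality$longest_gap_s, 8)
  expect_gte(det$quality$rating, 2L)
})

test_that("interval filter applies the running-mean tolerance rule", {
  # constant intervals all accepted
  ib <- filter_ibis(cumsum(rep(1, 100)))
  expect_true(all(ib$accepted))
  # a single halved interval (implied HR doubles) is rejected; intervals
  # are diff(beat times), so the 0.5 s gap is interval 50
  bt <- cumsum(c(rep(1, 50), 0.5, rep(1, 49)))
  ib2 <- filter_ibis(bt)
  expect_false(ib2$accepted[50])
  expect_equal(sum(!ib2$accepted), 1)
  # slow drift 1000 -> 1100 ms (~0.2% per beat) fully accepted
  drift_ib <- seq(1, 1.1, length.out = 50)
  ib3 <- filter_ibis(cumsum(drift_ib))
  expect_true(all(ib3$accepted))
  # physiological bounds are always enforced
  wild <- cumsum(c(rep(1, 60), 2.5, rep(1, 10), 0.2, rep(1, 10)))
  ib4 <- filter_ibis(wild)
  expect_true(all(ib4$interval_ms[ib4$accepted] >= 300))
  expect_true(all(ib4$interval_ms[ib4$accepted] <= 2000))
  # fewer than 2 beats -> empty series
  expect_length(filter_ibis(c(1))$interval_ms, 0)
})

test_that("blockwise HR averages accepted intervals by midpoint", {
  d <- tiny_design()
  ib <- filter_ibis(seq(0.5, 160, by = 1))
  bm <- hr_block_means(ib, d)
  expect_equal(bm$values, rep(60, 4))
  expect_equal(bm$units, "bpm")
  # alternating 1000 ms / 750 ms regimes across blocks
  bt <- numeric(0); t <- 0
  for (b in 1:4) {
    step <- if (b %% 2) 1 else 0.75
    onset <- (b - 1) * 40
    bt <- c(bt, seq(onset, onset + 40 - 1e-9, by = step))
  }
  ib2 <- filter_ibis(sort(unique(bt)), tolerance = 0.4)
  bm2 <- hr_block_means(ib2, d)
  expect_equal(bm2$values, c(60, 80, 60, 80), tolerance = 0.02)
  # rejected intervals do not contribute
  ib3 <- ib
  ib3$accepted[5] <- FALSE
  expect_equal(hr_block_means(ib3, d)$values, rep(60, 4))
})

test_that("volumewise HR interpolates instantaneous rate to scan times", {
  d <- tiny_design()
  ib <- filter_ibis(seq(0.5, 160, by = 1))
  expect_equal(hr_volume_means(ib, d), rep(60, 80), tolerance = 1e-10)
  # a step change produces an interpolated ramp crossing at the step
  bt <- c(seq(0, 80, by = 1), seq(81.5, 162, by = 1.5))
  ibs <- filter_ibis(bt, tolerance = 0.6)
  v <- suppressWarnings(hr_volume_means(ibs, d))
  expect_equal(v[10], 60, tolerance = 0.5)
  expect_equal(v[70], 40, tolerance = 0.5)
  expect_true(all(diff(v[35:55]) <= 1e-9))  # monotone down through the step
  # block averages of the volumewise trace agree with block means on
  # smooth traces
  set.seed(6)
  bt2 <- cumsum(0.8 + 0.04 * sin((1:230) / 15))
  ib2 <- filter_ibis(bt2)
  bv <- suppressWarnings(hr_volume_means(ib2, d))
  bm <- hr_block_means(ib2, d)
  blk <- scan_block_index(d)
  per_block <- tapply(bv[!is.na(blk)], blk[!is.na(blk)], mean)
  expect_lt(max(abs(per_block - bm$values)), 1)
})

test_that("HF-HRV spectral power is band-selective", {
  # 0.30 Hz modulation -> power concentrated in the 0.15-0.40 Hz band
  make_ibis <- function(freq, amp = 50, n = 600) {
    tk <- seq_len(n)  # approximate beat times at ~1 s spacing
    ibi_ms <- 1000 + amp * sin(2 * pi * freq * tk)
    bt <- cumsum(ibi_ms / 1000)
    structure(list(beat_times = c(0, bt), interval_ms = ibi_ms,
                   accepted = rep(TRUE, length(ibi_ms))),
              class = "ibi_series")
  }
  hf <- hf_hrv(make_ibis(0.30))
  lf_band <- c(0.04, 0.15)
  ib30 <- make_ibis(0.30)
  p_hf <- mean(hf$values)
  p_lf <- mean(hf_hrv(ib30, band = lf_band)$values)
  expect_gte(p_hf / (p_hf + p_lf), 0.95)
  # constant HR -> essentially no HF power
  hf0 <- hf_hrv(make_ibis(0.30, amp = 0))
  expect_lt(mean(hf0$values), 1e-6 * mean(hf$values))
  # 0.10 Hz modulation leaves < 5% of its power in the HF band
  ib10 <- make_ibis(0.10)
  p10_hf <- mean(hf_hrv(ib10)$values)
  p10_lf <- mean(hf_hrv(ib10, band = lf_band)$values)
  expect_lt(p10_hf / (p10_hf + p10_lf), 0.05)
  # recording shorter than one window errors informatively
  short <- filter_ibis(seq(0, 100, by = 1))
  expect_error(hf_hrv(short), "300")
})

test_that("band power integration satisfies Parseval", {
  set.seed(8)
  y <- rnorm(1200)
  fs <- 4
  bands <- list(c(0, 0.5), c(0.5, 1.0), c(1.0, 1.5), c(1.5, 2.0))
  # shift band edges to avoid double-counting shared bin frequencies
  total <- stresswave:::band_power(y, fs, c(0, 2))
  parts <- stresswave:::band_power(y, fs, c(0, 2 / 3 - 1e-9)) +
    stresswave:::band_power(y, fs, c(2 / 3, 4 / 3 - 1e-9)) +
    stresswave:::band_power(y, fs, c(4 / 3, 2))
  expect_equal(parts, total, tolerance = 1e-10)
  # total equals the variance of the detrended series
  fit <- lm(y ~ seq_along(y))
  expect_equal(total, mean(residuals(fit)^2), tolerance = 1e-8)
})

test_that("windows average into blocks and HR-HF correlation pools", {
  d <- default_design()
  wt <- structure(list(times = seq(15, 1485, by = 30),
                       values = seq_len(50), units = "ms2"),
                  class = "window_trace")
  bm <- window_block_means(wt, d)
  expect_length(bm$values, 15)
  # exact anticorrelation
  hr <- list(block_trace(c(60, 70, 80)), block_trace(c(65, 75, 85)))
  hf <- lapply(hr, function(b) block_trace(200 - b$values, "ms2"))
  expect_equal(hr_hf_correlation(hr, hf), -1)
  # constant trace -> undefined with warning
  const <- list(block_trace(rep(70, 3)))
  expect_warning(r0 <- hr_hf_correlation(const,
                                         list(block_trace(rep(5, 3), "ms2"))))
  expect_true(is.na(r0))
  # independent traces, large n -> near-zero correlation
  set.seed(9)
  hr2 <- replicate(200, block_trace(rnorm(15, 75, 5)), simplify = FALSE)
  hf2 <- replicate(200, block_trace(abs(rnorm(15, 30, 8)), "ms2"),
                   simplify = FALSE)
  expect_lt(abs(hr_hf_correlation(hr2, hf2)), 0.05)
})

test_that("physio recordings round-trip through BIDS-style files", {
  set.seed(10)
  rec <- physio_recording(rnorm(2000), 100, start_offset = -1.5)
  f <- file.path(tempdir(), "sub-01_physio.tsv.gz")
  write_physio(rec, f)
  rec2 <- read_physio(f)
  expect_equal(rec2$samples, rec$samples, tolerance = 1e-9)
  expect_equal(rec2$fs, 100)
  expect_equal(rec2$start_offset, -1.5)
})
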