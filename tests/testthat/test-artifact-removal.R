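# Scan-artifact detection, periodicity repair, temporal interpolation, and
# the line-noise variant.

test_that("detection threshold is 1.75 x SD of the rectified filtered signal", {
  rec <- make_noise_recording(duration = 5, n_channels = 3, seed = 1)
  ev <- detect_scan_artifacts(rec)
  y <- ecptools:::detection_signal(rec, detector_config())
  expect_equal(attr(ev, "threshold"), 1.75 * sd(y))
})

test_that("degenerate inputs: all-zero recording and short records", {
  zero <- ecp_recording(matrix(0, 5, FS), fs = FS)
  ev <- detect_scan_artifacts(zero)
  expect_length(ev$peak_times, 0)
  short <- ecp_recording(matrix(rnorm(FS / 10), 1), fs = FS)
  expect_error(detect_scan_artifacts(short), "3 scan periods")
})

test_that("injected artifacts at 5x noise SD are all detected within 1 ms", {
  rec <- make_noise_recording(duration = 20, n_channels = 5, seed = 2)
  noise_sd <- sd(rec$samples[1, ])
  spec <- artifact_spec("R", amplitude = 5 * noise_sd)
  inj <- inject_artifacts(rec, spec)
  ev <- enforce_periodicity(detect_scan_artifacts(inj$recording))
  apex <- inj$artifact_times + spec$scan_width_ms / 2000 # triangle center
  d <- vapply(apex, function(t) min(abs(ev$peak_times - t)), numeric(1))
  expect_gte(mean(d <= 1e-3), 0.99)
})

test_that("periodicity repair reproduces the worked example and the grid oracle", {
  raw <- artifact_events(c(0.100, 0.200, 0.353, 0.400), period_s = 0.1)
  out <- enforce_periodicity(raw, detector_config())
  expect_equal(out$peak_times, c(0.1, 0.2, 0.3, 0.4), tolerance = 1e-12)
  expect_identical(out$inserted, c(FALSE, FALSE, TRUE, FALSE))

  orc <- oracle_periodic_grid(c(0.100, 0.200, 0.353, 0.400), 0.1, 5e-3)
  expect_equal(sort(c(orc$kept, orc$inserted)), out$peak_times)
  expect_equal(orc$dropped, 0.353)
})

test_that("periodicity repair matches the grid oracle on random corruptions", {
  period <- 0.1; tol <- 5e-3
  for (seed in 1:20) {
    set.seed(seed)
    grid <- seq(0.05, 3, by = period)
    keep <- runif(length(grid)) > 0.15            # random misses
    jitter <- runif(sum(keep), -1e-3, 1e-3)
    spur <- runif(3, 0, 3)                        # spurious peaks
    times <- sort(c(grid[keep] + jitter, spur))
    # drop spurious peaks that accidentally land on the grid
    times <- times[!duplicated(round(times / period * 10))]
    out <- enforce_periodicity(artifact_events(times, period_s = period),
                               detector_config(min_evidence_frac = 0.4))
    orc <- oracle_periodic_grid(times, period, tol)
    expect_equal(length(out$peak_times),
                 length(orc$kept) + length(orc$inserted))
    # every retained/inserted peak is near a true grid point
    d <- vapply(out$peak_times,
                function(t) min(abs(t - grid)), numeric(1))
    expect_lt(max(d), tol + 1e-3)
    # postcondition: consecutive spacings are near-multiples of the period
    sp <- diff(out$peak_times)
    expect_true(all(abs(sp - round(sp / period) * period) <= 2 * tol))
  }
})

test_that("a suppressed artifact is restored by insertion near its true time", {
  rec <- make_noise_recording(duration = 20, n_channels = 5, seed = 4)
  spec <- artifact_spec("R", amplitude = 300)
  inj <- inject_artifacts(rec, spec)
  raw <- detect_scan_artifacts(inj$recording)
  apex <- inj$artifact_times + spec$scan_width_ms / 2000
  # simulate one scan falling below threshold: delete its raw peak
  drop_i <- 60
  near <- abs(raw$peak_times - apex[drop_i]) < 0.02
  raw$peak_times <- raw$peak_times[!near]
  out <- enforce_periodicity(raw)
  ins <- out$peak_times[out$inserted]
  expect_gte(length(ins), 1)
  expect_lt(min(abs(ins - apex[drop_i])), 2e-3)
})

test_that("fewer than 2 raw peaks returns unchanged with a warning", {
  raw <- artifact_events(0.5, period_s = 0.1)
  expect_warning(out <- enforce_periodicity(raw), "fewer than 2")
  expect_equal(out$peak_times, 0.5)
})

test_that("interpolation is local, exactly linear, and matches the closed form", {
  rec <- make_noise_recording(duration = 2, n_channels = 2, seed = 5)
  expect_identical(
    interpolate_segments(rec, artifact_events(numeric(0)))$samples,
    rec$samples)

  p <- 20000 # peak sample
  ev <- artifact_events((p - 1) / FS)
  out <- interpolate_segments(rec, ev)
  pre <- round(5e-3 * FS); post <- round(7e-3 * FS)
  a <- p - pre; b <- p + post
  for (ch in 1:2) {
    x0 <- rec$samples[ch, a - 1]; x1 <- rec$samples[ch, b + 1]
    expected <- x0 + (x1 - x0) * seq_len(b - a + 1) / (b - a + 2)
    expect_equal(as.numeric(out$samples[ch, a:b]), expected, tolerance = 1e-12)
    # zero second difference: exactly straight
    expect_equal(max(abs(diff(out$samples[ch, (a - 1):(b + 1)], differences = 2))),
                 0, tolerance = 1e-9)
  }
  # bit-exact outside the window
  keep <- setdiff(seq_len(ncol(rec$samples)), a:b)
  expect_identical(out$samples[, keep], rec$samples[, keep])
})

test_that("10 Hz peaks with the default -5..+7 ms window alter 12% of samples", {
  rec <- make_noise_recording(duration = 60, n_channels = 1, seed = 6)
  ev <- artifact_events(seq(0.05, 59.9, by = 0.1), period_s = 0.1)
  out <- interpolate_segments(rec, ev)
  expect_equal(attr(out, "altered_fraction"), 0.12, tolerance = 0.002)
})

test_that("artifact-free noise passes through nearly untouched", {
  rec <- make_noise_recording(duration = 20, n_channels = 5, seed = 8)
  res <- clean_recording(rec)
  expect_lt(res$altered_fraction, 0.01)
})

test_that("line-noise variant: threshold rule, sawtooth removal, clean input untouched", {
  rec <- make_noise_recording(duration = 5, n_channels = 2, seed = 9)
  lr <- remove_line_harmonics(rec)
  y <- ecptools:::detection_signal(rec, line_config())
  # threshold = 8 x mean of rectified filtered signal
  raw <- detect_scan_artifacts(rec) # unrelated; just ensure no interference
  expect_lt(attr(lr$recording, "altered_fraction"), 0.01)

  nz <- noise_model(white_sd = 5, pink_sd = 5, line_amp = 150,
                    line_shape = "sawtooth")
  recl <- make_noise_recording(duration = 10, n_channels = 3, seed = 10,
                               noise = nz)
  lr2 <- remove_line_harmonics(recl)
  expect_gt(length(lr2$events$peak_times), 0.9 * 10 * 60)
  sp <- diff(lr2$events$peak_times)
  expect_lt(max(abs(sp - round(sp * 60) / 60)), 5e-4)
})

test_that("full clean pass is near-idempotent", {
  fx <- make_unit_recording(duration = 20, seed = 11)
  inj <- inject_artifacts(fx$rec, artifact_spec("R"))
  c1 <- clean_recording(inj$recording)
  c2 <- clean_recording(c1$recording)
  extra <- mean(c2$recording$samples != c1$recording$samples)
  expect_lt(extra, 0.005)
})

test_that("cleaning leaves < 1 spike-band false positive per 100 scans at scan times", {
  fx <- make_unit_recording(duration = 30, seed = 12)
  inj <- inject_artifacts(fx$rec, artifact_spec("R"))
  res <- clean_recording(inj$recording)
  cfg <- spike_config()
  det <- detect_spikes(highpass_recording(res$recording, cfg), cfg)[[1]]
  # detections not explained by a true spike, within 2 ms of a scan time
  fp <- vapply(det, function(t)
    min(abs(fx$spikes - t)) > 1e-3 &&
      min(abs(inj$artifact_times + 0.00425 - t)) < 2e-3, TRUE)
  expect_lt(sum(fp), length(inj$artifact_times) / 100)
})
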