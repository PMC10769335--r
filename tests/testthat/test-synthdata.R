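# Ground-truth generators: spike trains, recordings, artifact templates,
# injection, and CV streams.

test_that("zero-rate and invalid spike-train arguments behave", {
  expect_length(gen_spike_train(cell_model("MSN", baseline_rate = 0), 10), 0)
  expect_error(gen_spike_train(cell_model("MSN"), -5), "positive")
})

test_that("homogeneous Poisson counts match the analytic mean", {
  # 0.5 Hz x 600 s -> mean 300; Monte-Carlo over seeds against the Poisson CI
  cell <- cell_model("MSN", baseline_rate = 0.5)
  counts <- vapply(1:50, function(s)
    length(gen_spike_train(cell, 600, seed = s)), numeric(1))
  # refractory censoring at 1 ms removes ~rate*refrac ~ 0.05% of spikes
  expect_gt(mean(counts), 300 - 3 * sqrt(300 / 50))
  expect_lt(mean(counts), 300 + 3 * sqrt(300 / 50))
})

test_that("spike trains are sorted, in range, censored, and seed-deterministic", {
  cell <- cell_model("TAN", baseline_rate = 8)
  st <- gen_spike_train(cell, 120, seed = 42)
  expect_false(is.unsorted(st))
  expect_true(all(st >= 0 & st < 120))
  expect_true(all(diff(st) >= 1e-3))
  expect_identical(st, gen_spike_train(cell, 120, seed = 42))
  expect_false(identical(st, gen_spike_train(cell, 120, seed = 43)))
})

test_that("TAN rate drops below 20% of baseline inside the cue pause", {
  cell <- cell_model("TAN", baseline_rate = 5)
  cues <- seq(5, 500, by = 5)
  st <- gen_spike_train(cell, 505, events = cues, seed = 9)
  m <- cell$event_modulation
  in_pause <- vapply(st, function(t) {
    rel <- t - cues[cues <= t]
    any(rel >= m$pause_latency_s & rel < m$pause_latency_s + m$pause_dur_s)
  }, TRUE)
  pause_rate <- sum(in_pause) / (length(cues) * m$pause_dur_s)
  expect_lt(pause_rate, 0.2 * 5)
})

test_that("rendering: zero units + zero noise gives zeros; white SD checks out; fs sets shape", {
  r0 <- render_recording(list(), 2, fs = FS, noise = NULL, duration = 1)
  expect_true(all(r0$recording$samples == 0))
  # default fs: 30000 samples per second
  expect_equal(ncol(r0$recording$samples), 30000)
  rw <- render_recording(list(), 1, fs = FS,
                         noise = noise_model(white_sd = 20, pink_sd = 0),
                         duration = 60, seed = 5)
  expect_equal(sd(rw$recording$samples[1, ]), 20, tolerance = 0.05)
})

test_that("rendered templates appear at ground-truth spike times", {
  st <- c(0.5, 1.0, 1.5)
  r <- render_recording(list(list(cell = cell_model("MSN"), times = st)),
                        1, fs = FS, noise = NULL, duration = 2)
  k <- round(st * FS) + 1
  expect_equal(as.numeric(r$recording$samples[1, k]),
               rep(-cell_model("MSN")$amplitude_uv, 3))
  expect_identical(r$ground_truth$spike_times_per_unit[[1]], st)
})

test_that("artifact templates obey amplitude, clipping, and width ordering", {
  expect_true(all(gen_artifact_template(artifact_spec("R", amplitude = 0), FS) == 0))
  rail <- gen_artifact_template(artifact_spec("RAIL", clip_level = 1000), FS)
  expect_equal(max(abs(rail)), 1000)
  widths <- vapply(c("R", "RC", "RAIL"), function(k) {
    tm <- gen_artifact_template(artifact_spec(k), FS)
    nz <- which(abs(tm) > 1e-9)
    (max(nz) - min(nz) + 1) / FS * 1000
  }, numeric(1))
  expect_lte(widths[["R"]], widths[["RC"]])
  expect_lte(widths[["RC"]], widths[["RAIL"]])
  # R pulse is the 8.5 ms scan triangle
  expect_equal(widths[["R"]], 8.5, tolerance = 0.01)
})

test_that("R and RC templates are amplitude-linear", {
  for (k in c("R", "RC")) {
    t1 <- gen_artifact_template(artifact_spec(k, amplitude = 400), FS)
    t2 <- gen_artifact_template(artifact_spec(k, amplitude = 800), FS)
    expect_equal(as.numeric(t2), 2 * as.numeric(t1), tolerance = 1e-12)
  }
})

test_that("injection: count formula, zero-amplitude identity, and locality", {
  rec <- make_noise_recording(duration = 10, n_channels = 2, seed = 3)
  spec <- artifact_spec("R", phase_s = 0.05)
  inj <- inject_artifacts(rec, spec)
  expect_length(inj$artifact_times, floor((10 - 0.05) / 0.1) + 1)

  inj0 <- inject_artifacts(rec, artifact_spec("R", amplitude = 0))
  expect_identical(inj0$recording$samples, rec$samples)

  # locality: samples outside artifact supports are bit-identical
  tmpl <- gen_artifact_template(spec, FS)
  touched <- rep(FALSE, ncol(rec$samples))
  for (t in inj$artifact_times) {
    a <- round(t * FS) + 1
    touched[a:min(ncol(rec$samples), a + length(tmpl) - 1)] <- TRUE
  }
  expect_identical(inj$recording$samples[, !touched], rec$samples[, !touched])
})

test_that("CV stream construction is linear and carries the 400 V/s triangle axis", {
  v <- cv_voltage_axis(850)
  expect_equal(length(v), 850)
  expect_equal(max(v), 1.3, tolerance = 2e-3)
  expect_lt(abs(v[1] - -0.4), 3e-3)
  expect_lt(abs(v[850] - -0.4), 3e-3)
  # 1.7 V up + 1.7 V down at 400 V/s = 8.5 ms
  expect_equal((1.3 - (-0.4)) * 2 / 400 * 1000, 8.5)

  s0 <- gen_cv_stream(5, noise_sd = 0)
  expect_true(all(apply(s0$frames, 2, function(col) all(col == col[1]))))

  s1 <- gen_cv_stream(20, transients = list(list(onset_s = 1, amplitude_nM = 50,
                                                 decay_s = Inf)),
                      noise_sd = 0)
  di <- background_subtract(s1, 1)
  sh <- ecptools:::analyte_shape("DA", 850)
  peak_frame <- di[15, ]
  expect_equal(peak_frame, 50 * 0.02 / max(abs(sh)) * sh, tolerance = 1e-9)
  expect_equal(diff(s1$scan_times[1:2]), 0.1)
})

test_that("seeded determinism holds end to end for the generators", {
  a <- render_recording(list(), 2, fs = FS, noise = noise_model(),
                        duration = 2, seed = 77)
  b <- render_recording(list(), 2, fs = FS, noise = noise_model(),
                        duration = 2, seed = 77)
  expect_identical(a$recording$samples, b$recording$samples)
  s1 <- gen_cv_stream(10, seed = 5)
  s2 <- gen_cv_stream(10, seed = 5)
  expect_identical(s1$frames, s2$frames)
})
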