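# High-pass filtering, threshold detection, waveform extraction, features,
# invalidation/clustering, unit summaries, and cell-type heuristics.

test_that("causal high-pass rejects DC and low frequencies, passes the spike band", {
  cfg <- spike_config()
  n <- FS * 2
  t <- (seq_len(n) - 1) / FS
  const <- ecp_recording(matrix(100, 1, n), fs = FS)
  out <- highpass_recording(const, cfg)
  expect_lt(max(abs(out$samples[1, (n / 2):n])), 1e-6)

  # frequency-response oracle for the 4-pole design
  gain <- function(f) {
    x <- ecp_recording(matrix(sin(2 * pi * f * t), 1), fs = FS)
    y <- highpass_recording(x, cfg)$samples[1, (n / 4):n]
    sd(y) / sd(sin(2 * pi * f * t))
  }
  expect_lt(20 * log10(gain(10)), -40)   # >= 40 dB down at 10 Hz
  expect_gt(20 * log10(gain(1000)), -3)  # < 3 dB loss at 1 kHz
  expect_error(highpass_recording(const, spike_config(hp_cutoff = FS)),
               "Nyquist")
})

test_that("causal filter output depends only on past input", {
  set.seed(2)
  x <- rnorm(FS)
  full <- highpass_recording(ecp_recording(matrix(x, 1), fs = FS))$samples[1, ]
  half <- highpass_recording(ecp_recording(matrix(x[1:(FS / 2)], 1),
                                           fs = FS))$samples[1, ]
  expect_equal(full[1:(FS / 2)], half, tolerance = 1e-12)
})

test_that("known injected templates are detected with sub-0.2 ms accuracy", {
  st <- seq(0.5, 10.3, by = 0.2) # 50 known times
  r <- render_recording(list(list(cell = cell_model("MSN"), times = st)),
                        1, fs = FS, noise = noise_model(), duration = 11,
                        seed = 21)
  cfg <- spike_config()
  det <- detect_spikes(highpass_recording(r$recording, cfg), cfg)[[1]]
  d <- vapply(st, function(t) min(abs(det - t)), numeric(1))
  expect_true(all(d <= 2e-4))
  expect_lt(attr(det, "threshold"), 0)
})

test_that("all-zero input yields no spikes; close crossings are censored", {
  zero <- ecp_recording(matrix(0, 1, FS), fs = FS)
  expect_length(detect_spikes(zero)[[1]], 0)

  # two troughs 0.4 ms apart -> one event (1 ms refractory censor)
  x <- numeric(FS)
  tm <- spike_template(FS, 0.25) * 300
  ti <- attr(tm, "trough_index")
  for (k in c(15000, 15000 + 12)) # 12 samples = 0.4 ms
    x[(k - ti + 1):(k - ti + length(tm))] <-
      x[(k - ti + 1):(k - ti + length(tm))] + tm
  x <- x + rnorm(FS, sd = 5)
  det <- detect_spikes(ecp_recording(matrix(x, 1), fs = FS))[[1]]
  expect_length(det, 1)
})

test_that("detection sensitivity and false-positive invariants hold at SNR >= 8", {
  fx <- make_unit_recording(duration = 60, cell_type = "MSN",
                            baseline_rate = 5, seed = 22)
  cfg <- spike_config()
  det <- detect_spikes(highpass_recording(fx$rec, cfg), cfg)[[1]]
  matched <- match_trains(fx$spikes, det, tol_ms = 0.5)
  expect_gte(matched / length(fx$spikes), 0.95)
  expect_lt((length(det) - matched) / 60, 0.2) # false positives < 0.2 Hz
})

test_that("waveform windows follow the 48-sample / 8-prethreshold contract", {
  cfg <- spike_config()
  expect_identical(cfg$waveform_len, 48L)
  expect_identical(cfg$pre_samples, 8L)
  expect_identical(round(1.6e-3 * FS), 48)
  expect_identical(round(0.267e-3 * FS), 8)

  x <- rnorm(2000)
  rec <- ecp_recording(matrix(x, 1), fs = FS)
  w <- extract_waveforms(rec, (1000 - 1) / FS, cfg)
  expect_equal(dim(w), c(1, 48))
  expect_equal(as.numeric(w), x[992:1039]) # event at sample 1000 -> 992..1039
  expect_message(w2 <- extract_waveforms(rec, (3 - 1) / FS, cfg), "skipped")
  expect_equal(nrow(w2), 0)
})

test_that("mean extracted waveform reproduces the injected template", {
  fx <- make_unit_recording(duration = 30, cell_type = "TAN",
                            baseline_rate = 5, seed = 23)
  cfg <- spike_config()
  filt <- highpass_recording(fx$rec, cfg)
  det <- detect_spikes(filt, cfg)[[1]]
  w <- extract_waveforms(filt, det, cfg)
  # compare to the filtered template (the data path is causally filtered)
  tm <- spike_template(FS, cell_model("TAN")$trough_to_peak_ms) * 300
  pad <- c(numeric(500), tm, numeric(500))
  ftm <- ecptools:::highpass_causal(pad, 250, FS, 4)
  ti <- which.min(ftm)
  ref <- ftm[(ti - 8):(ti + 39)]
  expect_gt(cor(colMeans(w), ref), 0.99)
})

test_that("features: zero and scaling identities; separable clusters", {
  z <- matrix(0, 2, 48)
  f <- compute_features(z)
  expect_equal(f$energy, c(0, 0))
  expect_equal(f$nl_energy, c(0, 0))

  w <- matrix(rnorm(48), 1)
  f1 <- compute_features(w)
  f2 <- compute_features(2 * w)
  expect_equal(f2$energy, 4 * f1$energy)
  expect_false("PC1" %in% names(f1)) # single waveform: no PC scores

  # two well-separated templates cluster cleanly in PC space
  t1 <- spike_template(FS, 0.25) * 200
  t2 <- spike_template(FS, 0.5) * 350
  wf <- rbind(t(replicate(40, t1[1:48] + rnorm(48, sd = 5))),
              t(replicate(40, t2[1:48] + rnorm(48, sd = 5))))
  ss <- spike_set(seq_len(80) * 0.1, wf, fs = FS)
  ss <- auto_invalidate_and_cluster(ss)
  truth <- rep(1:2, each = 40)
  tab <- table(truth, ss$unit_labels)
  expect_equal(length(unique(ss$unit_labels[ss$unit_labels > 0])), 2)
  expect_gte(sum(apply(tab, 1, max)) / 80, 0.95)
  sc <- as.matrix(ss$features[, c("PC1", "PC2")])
  sil <- cluster::silhouette(truth, dist(sc))
  expect_gt(mean(sil[, 3]), 0.5)
})

test_that("glitches and artifact-coincident events are invalidated", {
  tm <- spike_template(FS, 0.25) * 200
  wf <- t(replicate(50, tm[1:48] + rnorm(48, sd = 5)))
  wf <- rbind(wf, matrix(20 * tm[1:48], 2, 48, byrow = TRUE)) # 400x energy
  times <- c(seq_len(50) * 0.1, 5.55, 5.85)
  ss <- auto_invalidate_and_cluster(spike_set(times, wf, fs = FS))
  expect_true(all(ss$unit_labels[51:52] == 0))
  expect_gte(mean(ss$unit_labels[1:50] > 0), 0.95)

  ss2 <- auto_invalidate_and_cluster(spike_set(times, wf, fs = FS),
                                     artifact_times = c(0.5, 2.0005))
  expect_equal(ss2$unit_labels[5], 0L)  # within 1 ms of 0.5
  expect_equal(ss2$unit_labels[20], 0L) # within 1 ms of 2.0005
})

test_that("unit summaries: ISI mass, rate, and conservation", {
  su <- summarize_unit(c(0, 0.1, 0.2), bin_ms = 2, span = 0.3)
  expect_equal(su$mean_rate, 10)
  expect_equal(sum(su$isi_histogram$count), 2) # N - 1
  expect_equal(sum(su$isi_histogram$count[su$isi_histogram$isi_ms > 98 &
                                          su$isi_histogram$isi_ms < 102]), 2)

  st <- gen_spike_train(cell_model("TAN", baseline_rate = 6), 100, seed = 31)
  su2 <- summarize_unit(st, bin_ms = 1, span = 100)
  expect_equal(sum(su2$isi_histogram$count), length(st) - 1)
})

test_that("synthetic MSN and TAN units are classified by the heuristic", {
  trials <- gen_trials(40, seed = 32)
  msn <- cell_model("MSN")
  st_m <- gen_spike_train(msn, max(trials$RW_time) + 2, trials, seed = 33)
  tm_m <- spike_template(FS, msn$trough_to_peak_ms)
  su_m <- summarize_unit(st_m, matrix(tm_m, 1), fs = FS, bin_ms = 1,
                         span = max(trials$RW_time) + 2)
  expect_identical(su_m$putative_type, "MSN")

  tan <- cell_model("TAN")
  st_t <- gen_spike_train(tan, max(trials$RW_time) + 2, trials, seed = 34)
  tm_t <- spike_template(FS, tan$trough_to_peak_ms)
  su_t <- summarize_unit(st_t, matrix(tm_t, 1), fs = FS, bin_ms = 1,
                         span = max(trials$RW_time) + 2)
  expect_identical(su_t$putative_type, "TAN")
})
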