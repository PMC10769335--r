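# Shared fixture builders (constructed in code; nothing stored on disk).

FS <- 30000

# Short noisy recording with one tonic unit, used by several suites.
make_unit_recording <- function(duration = 20, cell_type = "TAN",
                                baseline_rate = 5, seed = 101,
                                n_channels = 1L, noise = noise_model()) {
  cell <- cell_model(cell_type, baseline_rate = baseline_rate)
  st <- gen_spike_train(cell, duration, seed = seed)
  units <- list(list(cell = cell_model(cell_type), times = st, channel = 1L))
  r <- render_recording(units, n_channels, fs = FS, noise = noise,
                        duration = duration, seed = seed + 1L)
  list(rec = r$recording, spikes = st, cell = cell)
}

# Noise-only recording.
make_noise_recording <- function(duration = 20, n_channels = 5L, seed = 7,
                                 noise = noise_model()) {
  render_recording(list(), n_channels, fs = FS, noise = noise,
                   duration = duration, seed = seed)$recording
}

# Brute-force periodic-grid oracle for periodicity repair: over candidate
# anchors, find the grid t0 + k*period best explaining the peaks, then report
# which peaks lie on it and which grid points are unfilled.
oracle_periodic_grid <- function(times, period, tol) {
  best <- NULL
  for (anchor in times) {
    k <- round((times - anchor) / period)
    on_grid <- abs(times - (anchor + k * period)) <= tol
    if (is.null(best) || sum(on_grid) > sum(best$on_grid))
      best <- list(anchor = anchor, on_grid = on_grid, k = k)
  }
  kept <- times[best$on_grid]
  kk <- best$k[best$on_grid]
  missing_k <- setdiff(seq(min(kk), max(kk)), kk)
  list(kept = kept,
       inserted = best$anchor + missing_k * period,
       dropped = times[!best$on_grid])
}

# Brute-force optimal-assignment spike matching (small instances): maximum
# one-to-one matching within tolerance via recursion.
oracle_match <- function(reference, test, tol) {
  n <- length(reference)
  if (n == 0L || length(test) == 0L) return(0L)
  rec <- function(i, used) {
    if (i > n) return(0L)
    best <- rec(i + 1L, used) # leave reference[i] unmatched
    for (j in seq_along(test)) {
      if (!used[j] && abs(test[j] - reference[i]) <= tol) {
        u <- used; u[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, u))
      }
    }
    best
  }
  rec(1L, rep(FALSE, length(test)))
}
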