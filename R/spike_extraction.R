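# Automated spike extraction: causal high-pass filtering, negative-threshold
# detection, fixed-length waveform extraction, energy / nonlinear-energy / PC
# features, outlier invalidation, clustering, and unit summaries.

#' Spike-extraction configuration
#'
#' Defaults follow the standard offline-sorter workflow: Butterworth
#' high-pass at 250 Hz (4-pole, forward only), negative threshold, 1.6 ms
#' (48-sample) waveforms with a 0.267 ms (8-sample) prethreshold period at
#' 30 kHz.
#'
#' @param hp_cutoff high-pass cutoff, Hz (default 250).
#' @param hp_poles filter order (default 4).
#' @param waveform_len waveform length, samples (default 48).
#' @param pre_samples prethreshold samples (default 8).
#' @param threshold_sd_mult threshold as a multiple of the robust SD
#'   (median absolute amplitude / 0.6745) of the filtered trace (default 4;
#'   applied negatively).
#' @param refractory_censor_ms censor interval after each accepted event, ms
#'   (default 1).
#' @param align_window_ms trough-alignment search window after the crossing,
#'   ms (default 1).
#' @param min_width_samples minimum number of consecutive sub-threshold
#'   samples for a crossing to count as an event (default 3, i.e., 0.1 ms
#'   at 30 kHz) — rejects single-sample noise excursions; real spike
#'   troughs dwell below threshold for several samples.
#' @param dead_time_ms detection lockout after each accepted event, ms
#'   (default 2): covers the extracted waveform and the causal high-pass
#'   filter's rebound undershoot, which would otherwise re-trigger the
#'   threshold on the same spike.
#' @return An object of class `spike_config`.
#' @export
spike_config <- function(hp_cutoff = 250, hp_poles = 4L, waveform_len = 48L,
                         pre_samples = 8L, threshold_sd_mult = 4,
                         refractory_censor_ms = 1, align_window_ms = 1,
                         min_width_samples = 3L, dead_time_ms = 2) {
  stopifnot(pre_samples < waveform_len, hp_cutoff > 0, hp_poles >= 1,
            threshold_sd_mult > 0, refractory_censor_ms >= 0,
            min_width_samples >= 1, dead_time_ms >= 0)
  structure(list(hp_cutoff = hp_cutoff, hp_poles = as.integer(hp_poles),
                 waveform_len = as.integer(waveform_len),
                 pre_samples = as.integer(pre_samples),
                 threshold_sd_mult = threshold_sd_mult,
                 refractory_censor_ms = refractory_censor_ms,
                 align_window_ms = align_window_ms,
                 min_width_samples = as.integer(min_width_samples),
                 dead_time_ms = dead_time_ms),
            class = "spike_config")
}

#' High-pass filter a recording for spike extraction
#'
#' Causal (forward-only) Butterworth high-pass on every channel. Forward-only
#' application matches the acquisition-style filtering whose group delay is
#' common to all events, so relative spike times are unaffected.
#'
#' @param rec an [ecp_recording()].
#' @param cfg a [spike_config()].
#' @return The filtered [ecp_recording()].
#' @export
highpass_recording <- function(rec, cfg = spike_config()) {
  if (cfg$hp_cutoff >= rec$fs / 2) stop("hp_cutoff at or above Nyquist")
  out <- rec
  for (ch in seq_len(nrow(rec$samples)))
    out$samples[ch, ] <- highpass_causal(rec$samples[ch, ], cfg$hp_cutoff,
                                         rec$fs, cfg$hp_poles)
  out
}

#' Detect spikes by negative-threshold crossing
#'
#' Per channel: threshold at `-threshold_sd_mult` x robust SD; each
#' negative-going crossing is aligned to the waveform trough within
#' `align_window_ms` after the crossing; events closer than the refractory
#' censor to the previous accepted event are dropped, as are events whose
#' extraction window would exceed the record bounds.
#'
#' @param filtered a high-pass-filtered [ecp_recording()].
#' @param cfg a [spike_config()].
#' @return List (one element per channel) of spike times in seconds; each
#'   element carries attribute `threshold` (microvolts, negative).
#' @export
detect_spikes <- function(filtered, cfg = spike_config()) {
  fs <- filtered$fs
  censor <- as.integer(round(max(cfg$refractory_censor_ms,
                                 cfg$dead_time_ms %||% 0) / 1000 * fs))
  align_n <- as.integer(round(cfg$align_window_ms / 1000 * fs))
  lapply(seq_len(nrow(filtered$samples)), function(ch) {
    x <- filtered$samples[ch, ]
    n <- length(x)
    thr <- -cfg$threshold_sd_mult * robust_sd(x)
    if (thr == 0) return(structure(numeric(0), threshold = 0))
    below <- x < thr
    cross <- which(!below[-n] & below[-1L]) + 1L
    mw <- cfg$min_width_samples %||% 1L
    troughs <- integer(0)
    last <- -Inf
    for (k in cross) {
      if (k - last < censor) next
      if (mw > 1L && (k + mw - 1L > n || any(x[k:(k + mw - 1L)] >= thr)))
        next
      b <- min(n, k + align_n)
      tr <- k + which.min(x[k:b]) - 1L
      if (tr - cfg$pre_samples < 1L ||
          tr - cfg$pre_samples + cfg$waveform_len - 1L > n) next
      if (tr - last < censor) next
      troughs <- c(troughs, tr)
      last <- tr
    }
    structure(sample_to_time(filtered, troughs), threshold = thr)
  })
}

#' Extract fixed-length spike waveforms
#'
#' An event at sample `k` (the aligned trough) yields samples
#' `[k - pre_samples, k - pre_samples + waveform_len - 1]`; with defaults at
#' 30 kHz, `[k - 8, k + 39]`. Out-of-bounds events are skipped.
#'
#' @param filtered a high-pass-filtered [ecp_recording()].
#' @param times event times, seconds (one channel).
#' @param cfg a [spike_config()].
#' @param channel channel index (default 1).
#' @return Matrix events x `waveform_len` (microvolts), with attribute
#'   `times` giving the retained event times.
#' @export
extract_waveforms <- function(filtered, times, cfg = spike_config(),
                              channel = 1L) {
  x <- filtered$samples[channel, ]
  n <- length(x)
  k <- time_to_sample(filtered, times)
  a <- k - cfg$pre_samples
  ok <- a >= 1L & (a + cfg$waveform_len - 1L) <= n
  if (any(!ok)) message(sum(!ok), " event(s) skipped: window out of bounds")
  a <- a[ok]
  w <- matrix(NA_real_, length(a), cfg$waveform_len)
  for (i in seq_along(a))
    w[i, ] <- x[a[i]:(a[i] + cfg$waveform_len - 1L)]
  attr(w, "times") <- times[ok]
  w
}

#' Waveform features: energy, nonlinear energy, PC scores
#'
#' Energy is the sum of squared samples; nonlinear (Teager) energy is the
#' mean of `x[n]^2 - x[n-1] * x[n+1]`; PC scores are projections onto the
#' principal components of the waveform covariance.
#'
#' @param waveforms events x samples matrix.
#' @param n_pcs number of PC scores to keep (default 3).
#' @return Data frame with `energy`, `nl_energy`, and `PC1..PCk` columns
#'   (PC columns absent when fewer than 2 waveforms).
#' @export
compute_features <- function(waveforms, n_pcs = 3L) {
  if (is.vector(waveforms)) waveforms <- matrix(waveforms, nrow = 1L)
  ne <- nrow(waveforms)
  energy <- rowSums(waveforms^2)
  nl <- apply(waveforms, 1L, function(x) {
    n <- length(x)
    mean(x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n])
  })
  out <- data.frame(energy = energy, nl_energy = nl)
  if (ne >= 2L) {
    pc <- stats::prcomp(waveforms, center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x))
    sc <- pc$x[, seq_len(k), drop = FALSE]
    colnames(sc) <- paste0("PC", seq_len(k))
    out <- cbind(out, as.data.frame(sc))
  }
  rownames(out) <- NULL
  out
}

#' A channel's detected spikes with waveforms, features, and unit labels
#'
#' @param times spike times, s (sorted).
#' @param waveforms events x samples matrix, microvolts.
#' @param features feature data frame from [compute_features()].
#' @param unit_labels integer per event; 0 = unsorted/invalidated.
#' @param fs sampling rate, Hz.
#' @param channel channel label.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(times, waveforms, features = NULL, unit_labels = NULL,
                      fs = 30000, channel = "ch1") {
  stopifnot(nrow(waveforms) == length(times))
  if (is.null(features)) features <- compute_features(waveforms)
  if (is.null(unit_labels)) unit_labels <- rep(1L, length(times))
  structure(list(times = times, waveforms = waveforms, features = features,
                 unit_labels = as.integer(unit_labels), fs = fs,
                 channel = channel),
            class = "spike_set")
}

#' @export
print.spike_set <- function(x, ...) {
  tab <- table(x$unit_labels)
  cat(sprintf("<spike_set> %s: %d events, units: %s\n", x$channel,
              length(x$times),
              paste(sprintf("%s(%d)", names(tab), tab), collapse = " ")))
  invisible(x)
}

#' Run the spike pipeline on one channel
#'
#' Detection, waveform extraction and feature computation composed; a
#' convenience wrapper returning a [spike_set()].
#'
#' @param filtered a high-pass-filtered [ecp_recording()].
#' @param cfg a [spike_config()].
#' @param channel channel index.
#' @return A [spike_set()] (all events provisionally labeled unit 1).
#' @export
extract_spikes <- function(filtered, cfg = spike_config(), channel = 1L) {
  times <- detect_spikes(filtered, cfg)[[channel]]
  w <- extract_waveforms(filtered, times, cfg, channel)
  tt <- attr(w, "times")
  spike_set(tt, w, fs = filtered$fs,
            channel = filtered$channel_labels[channel])
}

#' Invalidate outlier events and cluster the remainder
#'
#' Events whose energy or nonlinear energy lies beyond a robust outlier
#' bound (default median + 5 x IQR — an automated stand-in for the manual
#' prominence-based invalidation of glitch-like events), or that fall within
#' `artifact_tol_ms` of a known artifact time, are labeled 0 (invalid). PCs
#' are recomputed on the valid events, which are then k-means clustered in
#' PC1-PC2 with k chosen by mean silhouette over k = 1..4 (k = 1 is used
#' when no k >= 2 reaches silhouette 0.5).
#'
#' @param spikes a [spike_set()].
#' @param artifact_times known artifact times, s (default none).
#' @param iqr_mult outlier bound multiplier (default 5).
#' @param artifact_tol_ms exclusion half-window around artifact times, ms
#'   (default 1).
#' @param max_k maximum cluster count tried (default 4).
#' @param seed seed for k-means starts (default 1).
#' @return The [spike_set()] with updated `unit_labels` and recomputed PC
#'   features.
#' @export
auto_invalidate_and_cluster <- function(spikes, artifact_times = numeric(0),
                                        iqr_mult = 5, artifact_tol_ms = 1,
                                        max_k = 4L, seed = 1) {
  f <- spikes$features
  valid <- rep(TRUE, length(spikes$times))
  for (col in c("energy", "nl_energy")) {
    v <- f[[col]]
    bound <- stats::median(v) + iqr_mult * stats::IQR(v)
    valid <- valid & v <= bound
  }
  if (length(artifact_times) > 0L) {
    tol <- artifact_tol_ms / 1000
    for (i in seq_along(spikes$times))
      if (any(abs(spikes$times[i] - artifact_times) <= tol))
        valid[i] <- FALSE
  }
  labels <- integer(length(valid))
  nv <- sum(valid)
  if (nv >= 2L) {
    feats <- compute_features(spikes$waveforms[valid, , drop = FALSE])
    sc <- as.matrix(feats[, grep("^PC", names(feats)), drop = FALSE])
    if (ncol(sc) >= 1L && nv >= 4L) {
      sc2 <- sc[, seq_len(min(2L, ncol(sc))), drop = FALSE]
      best_k <- 1L
      best_sil <- 0.5 # k >= 2 must beat this to split
      d <- stats::dist(sc2)
      for (k in 2L:min(max_k, nv - 1L)) {
        km <- with_seed(seed, stats::kmeans(sc2, centers = k, nstart = 5L))
        sil <- mean(cluster::silhouette(km$cluster, d)[, 3L])
        if (sil > best_sil) { best_sil <- sil; best_k <- k }
      }
      cl <- if (best_k == 1L) rep(1L, nv)
            else with_seed(seed, stats::kmeans(sc2, centers = best_k,
                                               nstart = 5L))$cluster
      labels[valid] <- cl
      # write recomputed PCs back for the valid events
      for (nm in grep("^PC", names(feats), value = TRUE))
        spikes$features[[nm]][valid] <- feats[[nm]]
      if (any(!valid))
        for (nm in grep("^PC", names(spikes$features), value = TRUE))
          spikes$features[[nm]][!valid] <- NA_real_
    } else {
      labels[valid] <- 1L
    }
  } else {
    labels[valid] <- 1L
  }
  spikes$unit_labels <- labels
  spikes
}

#' Summarize one unit
#'
#' Mean +/- SD waveform, interspike-interval histogram (1 or 2 ms bins),
#' mean firing rate over the analyzed span, and a putative cell type from
#' [classify_cell_type()].
#'
#' @param times the unit's spike times, s.
#' @param waveforms events x samples matrix (may be `NULL`: rate/ISI only).
#' @param fs sampling rate, Hz.
#' @param bin_ms ISI histogram bin width: 1 or 2 ms.
#' @param span analyzed span in seconds (default: spike time range).
#' @param isi_max_ms upper ISI histogram limit, ms (default 500).
#' @return An object of class `unit_summary`.
#' @export
summarize_unit <- function(times, waveforms = NULL, fs = 30000,
                           bin_ms = c(1, 2), span = NULL,
                           isi_max_ms = 500) {
  bin_ms <- match.arg(as.character(bin_ms[1L]), c("1", "2"))
  bin_ms <- as.numeric(bin_ms)
  times <- sort(times)
  if (is.null(span)) span <- diff(range(times))
  rate <- if (span > 0) length(times) / span else NA_real_
  out <- list(n_spikes = length(times), mean_rate = rate, bin_ms = bin_ms)
  if (length(times) >= 2L) {
    isi_ms <- diff(times) * 1000
    breaks <- seq(0, max(isi_max_ms, ceiling(max(isi_ms) / bin_ms) * bin_ms),
                  by = bin_ms)
    h <- graphics::hist(isi_ms, breaks = breaks, plot = FALSE)
    out$isi_histogram <- data.frame(isi_ms = h$mids, count = h$counts)
    out$burst_index <- mean(isi_ms < 10)
  } else {
    out$isi_histogram <- NULL
    out$burst_index <- NA_real_
  }
  if (!is.null(waveforms) && nrow(waveforms) >= 1L) {
    out$mean_waveform <- colMeans(waveforms)
    out$sd_waveform <- apply(waveforms, 2L, stats::sd)
    out$trough_to_peak_ms <- trough_to_peak_ms(out$mean_waveform, fs)
  } else {
    out$trough_to_peak_ms <- NA_real_
  }
  out$putative_type <- classify_cell_type(out$mean_rate, out$burst_index,
                                          out$trough_to_peak_ms)
  class(out) <- "unit_summary"
  out
}

#' @export
print.unit_summary <- function(x, ...) {
  cat(sprintf(
    "<unit_summary> %d spikes, %.2f Hz, burst index %.3f, width %s ms -> %s\n",
    x$n_spikes, x$mean_rate, x$burst_index,
    if (is.na(x$trough_to_peak_ms)) "NA" else sprintf("%.2f", x$trough_to_peak_ms),
    x$putative_type))
  invisible(x)
}

# trough-to-subsequent-peak width of a mean waveform, ms
trough_to_peak_ms <- function(w, fs) {
  ti <- which.min(w)
  if (ti >= length(w)) return(NA_real_)
  pi <- ti + which.max(w[(ti + 1L):length(w)])
  (pi - ti) / fs * 1000
}

#' Heuristic striatal cell-type classification
#'
#' `TAN` if the mean rate is in 2-12 Hz and the waveform is broad
#' (trough-to-peak width above `width_split_ms`); `MSN` if the mean rate is
#' below 1 Hz with a burst index (fraction of ISIs < 10 ms) above 0.1;
#' otherwise `other`. Thresholds are heuristics reflecting the qualitative
#' firing/waveform differences between striatal projection neurons and
#' tonically active interneurons.
#'
#' @param mean_rate mean firing rate, Hz.
#' @param burst_index fraction of ISIs below 10 ms.
#' @param width_ms waveform trough-to-peak width, ms (`NA` allowed: the
#'   width condition is then waived for TAN).
#' @param width_split_ms narrow/broad split, ms (default 0.4).
#' @return `"MSN"`, `"TAN"`, or `"other"`.
#' @export
classify_cell_type <- function(mean_rate, burst_index, width_ms = NA,
                               width_split_ms = 0.4) {
  if (is.na(mean_rate)) return("other")
  if (mean_rate >= 2 && mean_rate <= 12 &&
      (is.na(width_ms) || width_ms > width_split_ms)) return("TAN")
  if (mean_rate < 1 && !is.na(burst_index) && burst_index > 0.1) return("MSN")
  "other"
}
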