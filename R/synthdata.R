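# Synthetic ground-truth generators: spike trains, waveform templates,
# background noise, FSCV scan artifacts of three morphologies, line noise,
# and cyclic-voltammogram streams. Everything is seeded and deterministic.

#' Background noise model for synthetic recordings
#'
#' White plus 1/f ("pink") background with optional 60 Hz line interference
#' and its harmonics.
#'
#' @param white_sd SD of the white component, microvolts (default 15).
#' @param pink_sd SD of the 1/f component, microvolts (default 10).
#' @param line_amp amplitude of the line-frequency fundamental, microvolts
#'   (default 0 = no line noise).
#' @param line_freq line frequency in Hz (default 60).
#' @param line_harmonics list of `c(harmonic_index, relative_amplitude)`
#'   pairs; harmonic indices must be >= 2.
#' @param line_shape `"sine"` for a pure tone per component, `"sawtooth"` for
#'   a broadband sawtooth at the fundamental (carries energy above 300 Hz,
#'   as seen when ground loops clip).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 15, pink_sd = 10, line_amp = 0,
                        line_freq = 60, line_harmonics = list(),
                        line_shape = c("sine", "sawtooth")) {
  line_shape <- match.arg(line_shape)
  stopifnot(white_sd >= 0, pink_sd >= 0, line_amp >= 0, line_freq > 0)
  for (h in line_harmonics)
    stopifnot(length(h) == 2L, h[1] >= 2, h[2] >= 0)
  structure(list(white_sd = white_sd, pink_sd = pink_sd, line_amp = line_amp,
                 line_freq = line_freq, line_harmonics = line_harmonics,
                 line_shape = line_shape),
            class = "noise_model")
}

# 1/f noise by spectral shaping of white noise, normalized to unit SD.
pink_noise <- function(n) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) # two-sided frequency index
  scale <- c(0, 1 / sqrt(freq[-1L]))
  p <- Re(stats::fft(f * scale, inverse = TRUE)) / n
  p / stats::sd(p)
}

# One channel of background noise; `phase` fixes the line-noise phase (rad).
gen_noise <- function(n, fs, model, phase = 0) {
  out <- numeric(n)
  if (model$white_sd > 0) out <- out + stats::rnorm(n, sd = model$white_sd)
  if (model$pink_sd > 0) out <- out + model$pink_sd * pink_noise(n)
  if (model$line_amp > 0) {
    tt <- (seq_len(n) - 1L) / fs
    if (model$line_shape == "sawtooth") {
      ph <- (model$line_freq * tt + phase / (2 * pi)) %% 1
      out <- out + model$line_amp * (2 * ph - 1)
    } else {
      out <- out + model$line_amp * sin(2 * pi * model$line_freq * tt + phase)
    }
    for (h in model$line_harmonics)
      out <- out + model$line_amp * h[2] *
        sin(2 * pi * model$line_freq * h[1] * tt + phase * h[1])
  }
  out
}

#' Biphasic extracellular spike waveform template
#'
#' Trough-dominant biphasic template: a negative Gaussian trough followed by
#' a smaller positive after-wave, peak-normalized so that the trough equals
#' -1. The trough-to-peak width is the conventional waveform-width measure
#' used to separate narrow (putative medium spiny neuron, MSN) from broad
#' (putative tonically active neuron, TAN) striatal units.
#'
#' @param fs sampling rate, Hz.
#' @param trough_to_peak_ms trough-to-peak width in ms.
#' @param duration_ms template support in ms (default 1.6).
#' @return Numeric vector with attribute `trough_index`.
#' @export
spike_template <- function(fs, trough_to_peak_ms = 0.25, duration_ms = 1.6) {
  n <- max(3L, round(duration_ms * fs / 1000))
  tt <- (seq_len(n) - 1L) / fs * 1000 # ms
  t_trough <- duration_ms * 0.3
  s1 <- trough_to_peak_ms / 2.5
  s2 <- trough_to_peak_ms / 2.2
  w <- -exp(-((tt - t_trough)^2) / (2 * s1^2)) +
    0.45 * exp(-((tt - t_trough - trough_to_peak_ms)^2) / (2 * s2^2))
  # smooth cosine taper to zero over the final 0.3 ms: a truncation step at
  # the support edge would ring through downstream causal filters
  taper_ms <- min(0.3, duration_ms / 4)
  edge <- tt > duration_ms - taper_ms - 1000 / fs
  w[edge] <- w[edge] *
    0.5 * (1 + cos(pi * (tt[edge] - (duration_ms - taper_ms - 1000 / fs)) /
                     taper_ms))
  w <- w / max(abs(w))
  structure(w, trough_index = which.min(w))
}

#' Synthetic striatal cell model
#'
#' Describes a unit of MSN or TAN character: baseline firing rate, event
#' modulation (a brief high-frequency burst for MSNs; a pause followed by a
#' rebound for TANs), and a peak-normalized waveform template. Defaults match
#' the field's qualitative picture: MSNs fire sparsely (< 1 Hz) with brief
#' bursts at behaviorally relevant events and have narrow waveforms; TANs
#' fire tonically at 2-12 Hz with cue-locked pauses and broad waveforms
#' (trough-to-peak width twice the MSN default).
#'
#' @param cell_type `"MSN"` or `"TAN"`.
#' @param baseline_rate baseline firing rate, Hz. Default 0.5 (MSN) or 5 (TAN).
#' @param event_modulation list controlling the rate response to each
#'   alignment event; see Details. `NULL` gives the per-type default.
#' @param amplitude_uv trough amplitude of the rendered waveform, microvolts
#'   (default 300 — a well-isolated unit; the causal 250 Hz high-pass used
#'   for sorting attenuates broad waveforms by up to half, and this default
#'   keeps the filtered-band SNR above 8 for both cell types under the
#'   default noise model).
#' @param trough_to_peak_ms waveform width; default 0.25 (MSN) or 0.5 (TAN).
#' @param template_duration_ms waveform support, default 1.6 ms.
#'
#' @details `event_modulation` fields: for MSN, `gain` (multiplicative rate
#' gain during the burst), `latency_s`, `dur_s`; for TAN, `pause_gain`
#' (multiplicative, near 0), `pause_latency_s`, `pause_dur_s`,
#' `rebound_gain`, `rebound_dur_s`. MSN default is a 30 ms burst at 200x
#' baseline (i.e., ~100 Hz instantaneous) 150 ms after the event; TAN default
#' is a 200 ms pause (gain 0.02) 50 ms after the event followed by a 200 ms
#' rebound at 2x.
#' @return An object of class `cell_model`.
#' @export
cell_model <- function(cell_type = c("MSN", "TAN"), baseline_rate = NULL,
                       event_modulation = NULL, amplitude_uv = 300,
                       trough_to_peak_ms = NULL, template_duration_ms = 1.6) {
  cell_type <- match.arg(cell_type)
  if (is.null(baseline_rate))
    baseline_rate <- if (cell_type == "MSN") 0.5 else 5
  stopifnot(baseline_rate >= 0, amplitude_uv >= 0)
  if (is.null(trough_to_peak_ms))
    trough_to_peak_ms <- if (cell_type == "MSN") 0.25 else 0.5
  if (is.null(event_modulation)) {
    event_modulation <- if (cell_type == "MSN") {
      list(gain = 200, latency_s = 0.15, dur_s = 0.03)
    } else {
      list(pause_gain = 0.02, pause_latency_s = 0.05, pause_dur_s = 0.2,
           rebound_gain = 2, rebound_dur_s = 0.2)
    }
  }
  structure(list(cell_type = cell_type, baseline_rate = baseline_rate,
                 event_modulation = event_modulation,
                 amplitude_uv = amplitude_uv,
                 trough_to_peak_ms = trough_to_peak_ms,
                 template_duration_ms = template_duration_ms),
            class = "cell_model")
}

# Instantaneous rate (Hz) of a cell at times tt given event times.
cell_rate_fun <- function(cell, tt, event_times = numeric(0)) {
  rate <- rep(cell$baseline_rate, length(tt))
  m <- cell$event_modulation
  for (ev in event_times) {
    if (cell$cell_type == "MSN") {
      idx <- tt >= ev + m$latency_s & tt < ev + m$latency_s + m$dur_s
      rate[idx] <- cell$baseline_rate * m$gain
    } else {
      p0 <- ev + m$pause_latency_s
      idx <- tt >= p0 & tt < p0 + m$pause_dur_s
      rate[idx] <- cell$baseline_rate * m$pause_gain
      idx2 <- tt >= p0 + m$pause_dur_s & tt < p0 + m$pause_dur_s + m$rebound_dur_s
      rate[idx2] <- cell$baseline_rate * m$rebound_gain
    }
  }
  rate
}

#' Generate a spike train from a cell model
#'
#' Inhomogeneous-Poisson draw from the cell's rate function (baseline plus
#' event modulation), by thinning, followed by refractory censoring of
#' inter-spike intervals below 1 ms. Deterministic given `seed`.
#'
#' @param cell a [cell_model()].
#' @param duration recording duration, seconds.
#' @param events alignment event times in seconds (numeric vector), or a
#'   trial table from [gen_trials()] whose `T_time` column is used, or `NULL`.
#' @param seed integer seed.
#' @param refractory_ms censoring interval, ms (default 1).
#' @return Sorted numeric vector of spike times in `[0, duration)`.
#' @export
gen_spike_train <- function(cell, duration, events = NULL, seed = 1,
                            refractory_ms = 1) {
  if (!is.numeric(duration) || duration <= 0)
    stop("duration must be positive")
  ev <- event_times_of(events)
  m <- cell$event_modulation
  rate_max <- cell$baseline_rate *
    max(1, m$gain %||% 1, m$rebound_gain %||% 1)
  if (rate_max == 0) return(numeric(0))
  with_seed(seed, {
    n_cand <- stats::rpois(1L, rate_max * duration)
    cand <- sort(stats::runif(n_cand, 0, duration))
    keep <- stats::runif(n_cand) < cell_rate_fun(cell, cand, ev) / rate_max
    st <- cand[keep]
    # refractory censoring: drop spikes closer than refractory_ms to the
    # previous retained spike
    if (length(st) > 1L) {
      out <- st[1L]
      last <- st[1L]
      for (t in st[-1L]) {
        if (t - last >= refractory_ms / 1000) {
          out <- c(out, t)
          last <- t
        }
      }
      st <- out
    }
    st
  })
}

event_times_of <- function(events) {
  if (is.null(events)) return(numeric(0))
  if (is.data.frame(events)) {
    if (!"T_time" %in% names(events)) stop("trial table lacks T_time")
    return(events$T_time)
  }
  as.numeric(events)
}

#' Render a synthetic multi-channel recording with paired ground truth
#'
#' Adds each unit's waveform template (trough-aligned at its spike times) to
#' its assigned channel and overlays per-channel background noise. Line-noise
#' phase is common across channels (coherent pickup), as are any scan
#' artifacts added later with [inject_artifacts()].
#'
#' @param units list of unit descriptions, each a list with elements `cell`
#'   (a [cell_model()]), `times` (spike times, s), and optionally `channel`
#'   (1-based; defaults to one unit per channel in order).
#' @param n_channels number of channels (>= 1).
#' @param fs sampling rate, Hz (default 30000).
#' @param noise a [noise_model()] or `NULL` for noiseless output.
#' @param duration recording duration, seconds.
#' @param seed integer seed (noise draw).
#' @return List with `recording` (an [ecp_recording()]) and `ground_truth`
#'   (spike times per unit, empty artifact times, line-noise phase).
#' @export
render_recording <- function(units = list(), n_channels = 1L, fs = 30000,
                             noise = NULL, duration = 10, seed = 1) {
  stopifnot(n_channels >= 1L, fs > 0, duration > 0)
  n <- round(duration * fs)
  x <- matrix(0, nrow = n_channels, ncol = n)
  spike_times <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    ch <- u$channel %||% ((i - 1L) %% n_channels + 1L)
    tmpl <- spike_template(fs, u$cell$trough_to_peak_ms,
                           u$cell$template_duration_ms) * u$cell$amplitude_uv
    if (length(tmpl) > n) stop("template longer than recording")
    ti <- attr(tmpl, "trough_index")
    for (t in u$times) {
      k <- as.integer(round(t * fs)) + 1L # trough sample
      a <- k - ti + 1L
      b <- a + length(tmpl) - 1L
      if (a < 1L || b > n) next
      x[ch, a:b] <- x[ch, a:b] + tmpl
    }
    spike_times[[i]] <- sort(u$times)
  }
  phase <- 0
  if (!is.null(noise)) {
    with_seed(split_seed(seed, 0L), {
      phase <- stats::runif(1L, 0, 2 * pi)
    })
    for (ch in seq_len(n_channels)) {
      ns <- with_seed(split_seed(seed, ch), gen_noise(n, fs, noise, phase))
      x[ch, ] <- x[ch, ] + ns
    }
  }
  rec <- ecp_recording(x, fs = fs)
  gt <- list(spike_times_per_unit = spike_times,
             artifact_times = numeric(0),
             line_noise_phase = phase,
             da_transients = list())
  list(recording = rec, ground_truth = gt)
}

#' FSCV scan-artifact specification
#'
#' Parameters of a synthetic scan artifact. Three morphologies are modeled,
#' reflecting how the scan couples into a neighboring electrophysiology
#' channel:
#' * `R` (resistive): a scaled copy of the triangular scan waveform — a
#'   symmetric triangular pulse of `scan_width_ms` duration.
#' * `RC` (resistive-capacitive): the same pulse low-passed by an RC time
#'   constant `rc_tau` (longer tail), plus brief charge-injection switching
#'   transients at the scan boundaries (the fast component of capacitive
#'   coupling at the slope discontinuities of the scan ramp).
#' * `RAIL` (saturating): the pulse clipped at the amplifier input range
#'   `clip_level`, followed by an underdamped (ringing) amplifier-recovery
#'   segment with time constant `recovery_tau` appended after the scan;
#'   its nonzero support is strictly wider than the R pulse.
#'
#' @param kind `"R"`, `"RC"`, or `"RAIL"`.
#' @param amplitude peak amplitude before clipping, microvolts. Defaults:
#'   800 (R, RC), 3000 (RAIL, which then saturates at `clip_level`).
#' @param rc_tau RC decay constant, ms (RC kind; default 4 — the tail
#'   extends past the default interpolation window, as the recovery deficit
#'   reported for RC-type artifacts implies).
#' @param clip_level amplifier input range, microvolts (default 1000, i.e.,
#'   +/- 1 mV).
#' @param recovery_tau amplifier settling constant after saturation, ms
#'   (RAIL kind; default 2).
#' @param scan_rate_hz scans per second (default 10).
#' @param scan_width_ms scan duration, ms (default 8.5 — the -0.4 to 1.3 to
#'   -0.4 V triangle at 400 V/s).
#' @param phase_s time of the first scan, seconds (default 0.05).
#' @param switch_frac amplitude of the fast switching transients relative to
#'   the pulse amplitude (RC/RAIL kinds; default 0.3 — switching glitches in
#'   combined recording setups are a substantial fraction of the coupled
#'   artifact).
#' @param channel_gains optional per-channel multipliers applied at
#'   injection (default: all 1 — fully coherent across channels).
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("R", "RC", "RAIL"), amplitude = NULL,
                          rc_tau = 4, clip_level = 1000, recovery_tau = 2.5,
                          scan_rate_hz = 10, scan_width_ms = 8.5,
                          phase_s = 0.05, switch_frac = 0.3,
                          channel_gains = NULL) {
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "RAIL") 3000 else 800
  stopifnot(amplitude >= 0, scan_rate_hz > 0,
            scan_width_ms > 0, scan_width_ms < 1000 / scan_rate_hz,
            clip_level > 0, rc_tau > 0, recovery_tau > 0)
  structure(list(kind = kind, amplitude = amplitude, rc_tau = rc_tau,
                 clip_level = clip_level, recovery_tau = recovery_tau,
                 scan_rate_hz = scan_rate_hz, scan_width_ms = scan_width_ms,
                 phase_s = phase_s, switch_frac = switch_frac,
                 channel_gains = channel_gains),
            class = "artifact_spec")
}

# Charge-injection switching transient at a scan boundary: a brief damped
# oscillation (underdamped headstage response to the slope discontinuity of
# the applied ramp), peak-normalized. Carries content well above the spike
# detection high-pass, unlike the smooth coupled ramp itself.
switch_transient <- function(fs, tau_ms = 0.8, f_ring = 800) {
  n <- max(3L, round(4 * tau_ms * fs / 1000))
  tt <- (seq_len(n) - 1L) / fs
  g <- exp(-tt / (tau_ms / 1000)) * cos(2 * pi * f_ring * tt)
  g / max(abs(g))
}

#' Generate one scan-artifact template
#'
#' Renders the artifact waveform for one scan at sampling rate `fs`; sample 1
#' is the scan onset. See [artifact_spec()] for the morphology definitions.
#'
#' @param spec an [artifact_spec()].
#' @param fs sampling rate, Hz.
#' @return Numeric vector (microvolts) with attribute `apex_index`, the
#'   sample of the scan apex (triangle center).
#' @export
gen_artifact_template <- function(spec, fs) {
  w <- round(spec$scan_width_ms * fs / 1000)
  half <- w / 2
  tri <- 1 - abs((seq_len(w) - 0.5) - half) / half # 0..1..0 triangle
  amp <- spec$amplitude
  if (amp == 0) {
    out <- numeric(w)
    attr(out, "apex_index") <- as.integer(round(half))
    return(out)
  }
  if (spec$kind == "R") {
    out <- amp * tri
  } else if (spec$kind == "RC") {
    tau_n <- spec$rc_tau * fs / 1000
    klen <- max(2L, round(4 * tau_n))
    kern <- exp(-(seq_len(klen) - 1L) / tau_n)
    kern <- kern / sum(kern)
    # full causal convolution: out[1] aligns with the scan onset
    out <- as.numeric(stats::convolve(amp * tri, rev(kern), type = "open"))
    sw <- switch_transient(fs)
    out <- add_at(out, sw * amp * spec$switch_frac, 1L)
    out <- add_at(out, -sw * amp * spec$switch_frac, w)
  } else { # RAIL
    pulse <- pmin(pmax(amp * tri, -spec$clip_level), spec$clip_level)
    sw <- switch_transient(fs)
    pulse <- add_at(pulse, sw * spec$clip_level * spec$switch_frac, 1L)
    pulse <- pmin(pmax(pulse, -spec$clip_level), spec$clip_level)
    tau_n <- spec$recovery_tau * fs / 1000
    rlen <- round(6.5 * tau_n)
    tr <- seq_len(rlen) - 1L
    taper <- (exp(-tr / tau_n) - exp(-rlen / tau_n)) / (1 - exp(-rlen / tau_n))
    ring <- -0.6 * spec$clip_level * taper *
      cos(2 * pi * 800 * tr / fs)
    out <- c(pulse, ring)
  }
  attr(out, "apex_index") <- as.integer(round(half))
  out
}

# add vector v into x starting at index `at`, clipping to bounds of x
add_at <- function(x, v, at) {
  a <- max(1L, at)
  b <- min(length(x), at + length(v) - 1L)
  if (b < a) return(x)
  x[a:b] <- x[a:b] + v[(a - at + 1L):(b - at + 1L)]
  x
}

#' Inject periodic scan artifacts into a recording
#'
#' Adds the artifact template at `phase_s, phase_s + 1/scan_rate_hz, ...` on
#' every channel (scaled by per-channel gains if given). For the RAIL kind
#' the sum is re-clipped at the amplifier input range, as a saturating
#' amplifier would. Samples outside the artifact supports are bit-identical
#' to the input.
#'
#' @param rec an [ecp_recording()].
#' @param spec an [artifact_spec()].
#' @return List with `recording` (contaminated) and `artifact_times`
#'   (template onset times, seconds).
#' @export
inject_artifacts <- function(rec, spec) {
  dur <- rec_duration(rec)
  period <- 1 / spec$scan_rate_hz
  if (dur < period) stop("recording shorter than one scan period")
  tmpl <- gen_artifact_template(spec, rec$fs)
  times <- seq(spec$phase_s, dur - 1e-12, by = period)
  times <- times[times >= 0]
  x <- rec$samples
  gains <- spec$channel_gains %||% rep(1, nrow(x))
  stopifnot(length(gains) == nrow(x))
  if (spec$amplitude > 0 && length(tmpl) > 0) {
    for (t in times) {
      a <- as.integer(round(t * rec$fs)) + 1L
      b <- min(ncol(x), a + length(tmpl) - 1L)
      if (a > ncol(x)) next
      seg <- seq_len(b - a + 1L)
      for (ch in seq_len(nrow(x))) {
        x[ch, a:b] <- x[ch, a:b] + gains[ch] * tmpl[seg]
        if (spec$kind == "RAIL")
          x[ch, a:b] <- pmin(pmax(x[ch, a:b], -spec$clip_level),
                             spec$clip_level)
      }
    }
  }
  out <- rec
  out$samples <- x
  list(recording = out, artifact_times = times)
}

# ---------------------------------------------------------------------------
# Cyclic-voltammogram stream synthesis

#' Triangular FSCV voltage axis
#'
#' The applied scan ramps from -0.4 V up to 1.3 V and back at 400 V/s, giving
#' an 8.5 ms scan digitized at `points` samples.
#'
#' @param points points per scan (default 850).
#' @return Numeric vector of applied voltages (V).
#' @export
cv_voltage_axis <- function(points = 850) {
  half <- points / 2
  i <- seq_len(points) - 0.5
  v <- ifelse(i <= half, -0.4 + 1.7 * i / half, 1.3 - 1.7 * (i - half) / half)
  as.numeric(v)
}

# Canonical analyte unit shapes on the voltage axis (current, nA, per unit of
# concentration-equivalent). DA: oxidation peak near +0.6 V on the anodic
# sweep, reduction trough near -0.2 V on the cathodic sweep.
analyte_shape <- function(class = c("DA", "pH", "movement"), points = 850) {
  class <- match.arg(class)
  v <- cv_voltage_axis(points)
  half <- points / 2
  up <- seq_len(points) <= half
  if (class == "DA") {
    s <- exp(-((v - 0.6)^2) / (2 * 0.12^2)) * up -
      0.6 * exp(-((v + 0.2)^2) / (2 * 0.15^2)) * !up
  } else if (class == "pH") {
    s <- 0.7 * exp(-((v - 0.2)^2) / (2 * 0.5^2)) -
      0.5 * exp(-((v - 1.0)^2) / (2 * 0.3^2)) * up
  } else {
    # movement artifact: broad baseline tilt plus a sharp feature at the apex
    s <- 0.8 * (v + 0.4) / 1.7 + exp(-((v - 1.25)^2) / (2 * 0.05^2))
  }
  s / sqrt(sum(s^2)) # unit-norm shape
}

#' Generate a synthetic library of training standards
#'
#' Builds background-subtracted training voltammograms for dopamine (at known
#' concentrations), pH, and movement-artifact classes from the canonical
#' analyte shapes, with additive current noise.
#'
#' @param da_concentrations known DA concentrations, nM (default
#'   `c(25, 50, 100, 200)`).
#' @param n_rep replicates per training condition (default 3).
#' @param noise_sd current noise SD, nA (default 0.05). Background
#'   subtraction of a stream doubles its noise variance, so training
#'   standards should carry at least `sqrt(2)` times the stream's per-frame
#'   noise for the Q tolerance to be calibrated correctly.
#' @param points points per scan (default 850).
#' @param sensitivity electrode sensitivity: peak DA current (nA) per nM
#'   (default 0.02).
#' @param seed integer seed.
#' @return List with `cvs` (rows = training CVs), `labels`, `concentrations`
#'   (NA for non-DA rows) — input to [fit_standards()].
#' @export
gen_standards <- function(da_concentrations = c(25, 50, 100, 200),
                          n_rep = 3, noise_sd = 0.05, points = 850,
                          sensitivity = 0.02, seed = 1) {
  shapes <- list(DA = analyte_shape("DA", points),
                 pH = analyte_shape("pH", points),
                 movement = analyte_shape("movement", points))
  da_peak <- max(abs(shapes$DA))
  rows <- list(); labels <- character(0); conc <- numeric(0)
  with_seed(seed, {
    for (c_nM in da_concentrations) for (r in seq_len(n_rep)) {
      amp <- c_nM * sensitivity / da_peak
      rows[[length(rows) + 1L]] <- amp * shapes$DA +
        stats::rnorm(points, sd = noise_sd)
      labels <- c(labels, "DA"); conc <- c(conc, c_nM)
    }
    # pH shifts are subtle; movement artifacts are large — train each class
    # at magnitudes it actually presents, so the fitted directions are clean
    amps <- list(pH = c(1, 2), movement = c(4, 8))
    for (cls in c("pH", "movement")) for (r in seq_len(n_rep)) for (a in amps[[cls]]) {
      rows[[length(rows) + 1L]] <- a * shapes[[cls]] +
        stats::rnorm(points, sd = noise_sd)
      labels <- c(labels, cls); conc <- c(conc, NA_real_)
    }
  })
  list(cvs = do.call(rbind, rows), labels = labels, concentrations = conc,
       sensitivity = sensitivity, points = points)
}

#' Generate a synthetic cyclic-voltammogram stream
#'
#' Each frame is a background CV plus scaled analyte shapes for any active
#' transients plus current noise; frames are spaced 100 ms apart (10 Hz
#' scan application). Dopamine transients rise instantaneously at onset and
#' decay exponentially.
#'
#' @param n_scans number of frames.
#' @param transients list of transients, each
#'   `list(onset_s=, amplitude_nM=, decay_s=, class="DA")` (`class` may also
#'   be `"movement"` with `amplitude_nM` read as a scale factor in nA-norm
#'   units).
#' @param noise_sd per-frame current noise SD, nA (default 0.02 — below the
#'   0.05 nA standards default by more than `1/sqrt(2)`, so background
#'   subtraction keeps the residual Q within the standards' tolerance).
#' @param points points per scan (default 850).
#' @param sensitivity peak DA current (nA) per nM (default 0.02; must match
#'   the standards library used for projection).
#' @param scan_period_s frame spacing, s (default 0.1).
#' @param background optional background CV (length `points`); default is a
#'   large smooth non-faradaic background.
#' @param seed integer seed.
#' @return An object of class `cv_stream`: list with `frames`
#'   (scans x points, nA), `voltage_axis`, `scan_times`, and `ground_truth`
#'   (true DA concentration per scan, nM; movement flags).
#' @export
gen_cv_stream <- function(n_scans, transients = list(), noise_sd = 0.02,
                          points = 850, sensitivity = 0.02,
                          scan_period_s = 0.1, background = NULL, seed = 1) {
  stopifnot(n_scans >= 1)
  v <- cv_voltage_axis(points)
  if (is.null(background))
    background <- 200 * sin(pi * (seq_len(points) - 0.5) / points) + 50 * v
  stopifnot(length(background) == points)
  shapes <- list(DA = analyte_shape("DA", points),
                 movement = analyte_shape("movement", points))
  da_peak <- max(abs(shapes$DA))
  times <- (seq_len(n_scans) - 1L) * scan_period_s
  true_da <- numeric(n_scans)
  movement_scale <- numeric(n_scans)
  frames <- matrix(rep(background, n_scans), nrow = n_scans, byrow = TRUE)
  for (tr in transients) {
    cls <- tr$class %||% "DA"
    active <- which(times >= tr$onset_s)
    amp_t <- tr$amplitude_nM * exp(-(times[active] - tr$onset_s) /
                                     (tr$decay_s %||% Inf))
    if (cls == "DA") {
      true_da[active] <- true_da[active] + amp_t
    } else {
      movement_scale[active] <- movement_scale[active] + amp_t
    }
  }
  frames <- frames + (true_da * sensitivity / da_peak) %o% shapes$DA +
    movement_scale %o% shapes$movement
  if (noise_sd > 0)
    frames <- frames + with_seed(seed,
      matrix(stats::rnorm(n_scans * points, sd = noise_sd), nrow = n_scans))
  structure(list(frames = frames, voltage_axis = v, scan_times = times,
                 points_per_scan = points,
                 ground_truth = list(da_nM = true_da,
                                     movement = movement_scale > 0)),
            class = "cv_stream")
}

#' @export
print.cv_stream <- function(x, ...) {
  cat(sprintf("<cv_stream> %d scans x %d points, %.1f s at %.0f ms spacing\n",
              nrow(x$frames), x$points_per_scan,
              utils::tail(x$scan_times, 1L),
              1000 * diff(x$scan_times[1:2])))
  invisible(x)
}
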