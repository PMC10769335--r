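# Readers/writers: recordings and CV streams as float32 flat binary with a
# JSON sidecar; events/trials/results as CSV; pipeline configuration as YAML.

#' Write / read a recording container
#'
#' A recording is stored as `<stem>.json` (metadata: `fs`, `t0`,
#' `channel_labels`, `n_channels`, `n_samples`, `dtype`, `byte_order`) plus
#' `<stem>.f32` (channel-major little-endian float32 samples, microvolts).
#' The round trip is lossless for float32 samples.
#'
#' @param rec an [ecp_recording()].
#' @param stem path stem (no extension).
#' @param meta extra metadata fields stored in the sidecar (e.g., the
#'   producing config hash).
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns an [ecp_recording()].
#' @export
write_recording <- function(rec, stem, meta = list()) {
  stopifnot(inherits(rec, "ecp_recording"))
  side <- c(list(format = "ecp-recording-v1", fs = rec$fs, t0 = rec$t0,
                 channel_labels = rec$channel_labels,
                 n_channels = nrow(rec$samples),
                 n_samples = ncol(rec$samples),
                 dtype = "float32", byte_order = "little"), meta)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  # channel-major: channel 1's samples first
  writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  jf <- paste0(stem, ".json")
  if (!file.exists(jf)) stop("no sidecar file: ", jf)
  side <- jsonlite::read_json(jf, simplifyVector = TRUE)
  for (f in c("fs", "n_channels", "n_samples"))
    if (is.null(side[[f]])) stop("sidecar missing required field \"", f, "\"")
  bf <- paste0(stem, ".f32")
  n <- side$n_channels * side$n_samples
  con <- file(bf, "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  if (length(x) != n) stop("binary payload shorter than declared shape")
  ecp_recording(matrix(x, nrow = side$n_channels, byrow = TRUE),
                fs = side$fs, t0 = side$t0 %||% 0,
                channel_labels = side$channel_labels)
}

#' Write / read a CV stream container
#'
#' `<stem>.json` holds `n_scans`, `points_per_scan`, `scan_times`, and
#' `voltage_axis`; `<stem>.f32` holds the scan-major float32 current frames
#' (nA).
#'
#' @param stream a `cv_stream`.
#' @param stem path stem.
#' @return `write_cv_stream` returns `stem` invisibly; `read_cv_stream` a
#'   `cv_stream`.
#' @export
write_cv_stream <- function(stream, stem) {
  stopifnot(inherits(stream, "cv_stream"))
  side <- list(format = "cv-stream-v1", n_scans = nrow(stream$frames),
               points_per_scan = stream$points_per_scan,
               scan_times = stream$scan_times,
               voltage_axis = stream$voltage_axis)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(stream$frames)), con, size = 4L, endian = "little")
  invisible(stem)
}

#' @rdname write_cv_stream
#' @export
read_cv_stream <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  for (f in c("n_scans", "points_per_scan"))
    if (is.null(side[[f]])) stop("sidecar missing required field \"", f, "\"")
  con <- file(paste0(stem, ".f32"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = side$n_scans * side$points_per_scan,
               size = 4L, endian = "little")
  structure(list(frames = matrix(x, nrow = side$n_scans, byrow = TRUE),
                 voltage_axis = side$voltage_axis,
                 scan_times = side$scan_times,
                 points_per_scan = side$points_per_scan,
                 ground_truth = NULL),
            class = "cv_stream")
}

#' Write / read behavioral event tables
#'
#' CSV with a header; times in seconds. Trial tables (columns `C_time`,
#' `T_time`, `RW_time`) are validated: within-trial events must be ordered
#' `C < T < RW`, and violations raise an error naming the offending trial.
#' `offset_s` shifts all time columns, supporting alignment of the FSCV and
#' electrophysiology clocks via shared trial-start codes.
#'
#' @param events data frame (e.g., a [gen_trials()] table).
#' @param path CSV path.
#' @param offset_s clock offset added to every `*_time`/`time_s` column on
#'   read (default 0).
#' @return `read_events` returns the validated data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, offset_s = 0) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcols <- grep("(_time|^time_s)$", names(out), value = TRUE)
  for (cc in tcols) out[[cc]] <- out[[cc]] + offset_s
  if (all(c("C_time", "T_time", "RW_time") %in% names(out)) && nrow(out) > 0L) {
    bad <- which(!(out$C_time < out$T_time & out$T_time < out$RW_time))
    if (length(bad))
      stop("unordered within-trial events in trial(s): ",
           paste(bad, collapse = ", "))
    class(out) <- c("trial_table", "data.frame")
  }
  out
}

# ---------------------------------------------------------------------------
# Pipeline configuration (YAML)

config_sections <- list(
  simulate = c("duration_s", "n_channels", "fs", "artifact_kind",
               "artifact_amplitude", "scan_rate_hz", "white_sd", "pink_sd",
               "line_amp", "n_trials", "n_scans", "cv_noise_sd"),
  clean = c("band_low", "band_high", "threshold_mult", "scan_rate_hz",
            "period_tolerance_ms", "interp_pre_ms", "interp_post_ms",
            "min_evidence_frac", "line_noise"),
  sort = c("hp_cutoff", "hp_poles", "waveform_len", "pre_samples",
           "threshold_sd_mult", "refractory_censor_ms", "bin_ms"),
  fscv = c("ref_scan", "r_null", "q_quantile"),
  validate = c("kinds", "tol_ms"),
  align = c("event", "window", "bin", "split_by"))

#' Read / write the pipeline configuration
#'
#' YAML file with sections `simulate`, `clean`, `sort`, `fscv`, `validate`,
#' `align` plus top-level `seed` and `log_level`. Unknown sections or keys
#' are rejected.
#'
#' @param path YAML path.
#' @param cfg configuration list.
#' @return `read_config` returns the validated list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known_top <- c(names(config_sections), "seed", "log_level", "paths")
  extra <- setdiff(names(cfg), known_top)
  if (length(extra)) stop("unknown config section(s): ",
                          paste(extra, collapse = ", "))
  for (sec in intersect(names(cfg), names(config_sections))) {
    bad <- setdiff(names(cfg[[sec]]), config_sections[[sec]])
    if (length(bad)) stop("unknown key(s) in section ", sec, ": ",
                          paste(bad, collapse = ", "))
  }
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Short content hash of a configuration
#'
#' FNV-1a over the YAML serialization; logged with every pipeline output so
#' that files can be traced to the configuration that produced them.
#'
#' @param cfg configuration list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(cfg))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}
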