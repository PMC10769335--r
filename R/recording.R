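#' Multi-channel extracellular voltage recording
#'
#' Container for a continuous multi-channel extracellular recording: a
#' channels-by-time voltage matrix in microvolts with its sampling rate,
#' start time, and channel labels. Channel labels follow the c/p convention
#' for caudate and putamen sites (e.g., `"c34"`, `"p15"`) but are free-form.
#'
#' @param samples numeric matrix, channels x time, microvolts. A vector is
#'   treated as a single channel.
#' @param fs sampling rate in Hz (default 30000).
#' @param t0 time of the first sample in seconds (default 0).
#' @param channel_labels character vector of channel names; defaults to
#'   `ch1, ch2, ...`.
#' @return An object of class `ecp_recording`.
#' @examples
#' rec <- ecp_recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' rec
#' @export
ecp_recording <- function(samples, fs = 30000, t0 = 0, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  stopifnot(length(channel_labels) == nrow(samples))
  structure(
    list(samples = samples, fs = fs, t0 = t0,
         channel_labels = as.character(channel_labels)),
    class = "ecp_recording")
}

#' @export
print.ecp_recording <- function(x, ...) {
  cat(sprintf("<ecp_recording> %d channel(s) x %d samples @ %g Hz (%.3f s), t0 = %g s\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$t0))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.ecp_recording <- function(object, ...) {
  s <- object$samples
  out <- data.frame(
    channel = object$channel_labels,
    mean_uV = rowMeans(s),
    sd_uV = apply(s, 1L, stats::sd),
    min_uV = apply(s, 1L, min),
    max_uV = apply(s, 1L, max))
  rownames(out) <- NULL
  out
}

#' @export
plot.ecp_recording <- function(x, channels = seq_len(nrow(x$samples)),
                               tlim = NULL, offset_uV = NULL, ...) {
  tt <- x$t0 + (seq_len(ncol(x$samples)) - 1L) / x$fs
  keep <- if (is.null(tlim)) rep(TRUE, length(tt)) else tt >= tlim[1] & tt <= tlim[2]
  s <- x$samples[channels, keep, drop = FALSE]
  if (is.null(offset_uV)) offset_uV <- 4 * max(apply(s, 1L, stats::sd), 1e-9)
  graphics::plot(NA, xlim = range(tt[keep]),
                 ylim = c(-offset_uV, offset_uV * length(channels)),
                 xlab = "time (s)", ylab = "voltage (uV, offset per channel)", ...)
  for (i in seq_along(channels))
    graphics::lines(tt[keep], s[i, ] + (i - 1L) * offset_uV)
  graphics::axis(4, at = (seq_along(channels) - 1L) * offset_uV,
                 labels = x$channel_labels[channels], las = 1, tick = FALSE)
  invisible(x)
}

# duration in seconds
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

# time (s) -> 1-based sample index (nearest)
time_to_sample <- function(rec, t) as.integer(round((t - rec$t0) * rec$fs)) + 1L

sample_to_time <- function(rec, i) rec$t0 + (i - 1L) / rec$fs
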