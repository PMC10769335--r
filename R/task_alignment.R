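# Peri-event alignment and condition-split trial averaging of spike and
# dopamine signals, plus the synthetic behavioral-trial generator.

#' Generate a synthetic behavioral trial table
#'
#' Each trial: central cue `C`, peripheral target `T` after a fixed central
#' fixation, and reward `RW` after the target fixation. The mapping between
#' target direction (left/right) and reward size (small/large) switches
#' every 20-30 trials (uniformly drawn block lengths).
#'
#' @param n_trials number of trials.
#' @param seed integer seed.
#' @param c_fix_s central fixation (C to T latency), s (default 1.6).
#' @param t_rw_s target fixation (T to RW latency), s (default 4).
#' @param iti_s inter-trial interval after RW, s (default 2).
#' @param t_start start time of the first C cue, s (default 1).
#' @return Data frame of class `trial_table` with columns `trial`, `C_time`,
#'   `T_time`, `RW_time`, `target_dir` (`left`/`right`), `reward_size`
#'   (`small`/`large`), `block`.
#' @export
gen_trials <- function(n_trials, seed = 1, c_fix_s = 1.6, t_rw_s = 4,
                       iti_s = 2, t_start = 1) {
  if (n_trials == 0L) {
    out <- data.frame(trial = integer(0), C_time = numeric(0),
                      T_time = numeric(0), RW_time = numeric(0),
                      target_dir = character(0), reward_size = character(0),
                      block = integer(0))
    class(out) <- c("trial_table", "data.frame")
    return(out)
  }
  with_seed(seed, {
    # block lengths uniform in 20..30 until n_trials covered
    lens <- integer(0)
    while (sum(lens) < n_trials)
      lens <- c(lens, sample(20:30, 1L))
    block <- rep(seq_along(lens), lens)[seq_len(n_trials)]
    # mapping alternates per block: odd blocks left->large
    left_large <- block %% 2L == 1L
    dir <- sample(c("left", "right"), n_trials, replace = TRUE)
    size <- ifelse((dir == "left") == left_large, "large", "small")
    period <- c_fix_s + t_rw_s + iti_s
    C <- t_start + (seq_len(n_trials) - 1L) * period
    out <- data.frame(trial = seq_len(n_trials), C_time = C,
                      T_time = C + c_fix_s, RW_time = C + c_fix_s + t_rw_s,
                      target_dir = dir, reward_size = size, block = block)
    class(out) <- c("trial_table", "data.frame")
    out
  })
}

#' Align spikes or a dopamine trace to behavioral events
#'
#' Spike input (numeric times) is binned into per-trial firing rates (Hz);
#' trace input (a `da_trace` or any data frame with `time_s` and a value
#' column) is averaged within bins, with nulled (`NA`) samples excluded
#' rather than zero-filled. Trials whose window exceeds the data span are
#' dropped with a warning.
#'
#' @param x spike times (numeric vector) or a `da_trace` data frame.
#' @param events alignment event times, s (one per trial).
#' @param window `c(start, end)` around each event, s (default `c(-2, 6)`).
#' @param bin bin width, s (default 0.05 for spikes; 0.1 — the scan
#'   interval — is natural for dopamine).
#' @param labels optional data frame of per-trial condition labels
#'   (e.g., columns of a [gen_trials()] table), attached for
#'   [condition_average()].
#' @param span data span `c(t_min, t_max)` used for edge-trial dropping;
#'   defaults to the span of `x`.
#' @return A matrix trials x bins of class `aligned_matrix` with attributes
#'   `bin_centers`, `window`, `bin`, `labels`, `kind`.
#' @export
align_to_events <- function(x, events, window = c(-2, 6), bin = 0.05,
                            labels = NULL, span = NULL) {
  if (length(events) == 0L) stop("no alignment events")
  stopifnot(length(window) == 2L, window[2] > window[1], bin > 0)
  edges <- seq(window[1], window[2], by = bin)
  if (abs(utils::tail(edges, 1L) - window[2]) > 1e-9)
    edges <- c(edges, window[2])
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  is_trace <- is.data.frame(x)
  if (is.null(span)) {
    span <- if (is_trace) range(x$time_s) else
      if (length(x)) range(x) else c(-Inf, Inf)
  }
  ok <- events + window[1] >= span[1] & events + window[2] <= span[2]
  if (any(!ok)) {
    warning(sum(!ok), " edge trial(s) dropped")
    events <- events[ok]
    if (!is.null(labels)) labels <- labels[ok, , drop = FALSE]
  }
  out <- matrix(NA_real_, length(events), length(centers))
  if (is_trace) {
    vcol <- if ("delta_da" %in% names(x)) "delta_da" else names(x)[2L]
    for (i in seq_along(events)) {
      rel <- x$time_s - events[i]
      b <- findInterval(rel, edges, rightmost.closed = TRUE)
      inw <- b >= 1L & b <= length(centers)
      v <- x[[vcol]][inw]
      bb <- b[inw]
      out[i, ] <- vapply(seq_along(centers), function(j) {
        vj <- v[bb == j & !is.na(v)]
        if (length(vj)) mean(vj) else NA_real_
      }, numeric(1))
    }
  } else {
    for (i in seq_along(events)) {
      rel <- x - events[i]
      h <- graphics::hist(rel[rel >= window[1] & rel <= window[2]],
                          breaks = edges, plot = FALSE)
      out[i, ] <- h$counts / diff(edges) # Hz
    }
  }
  structure(out, bin_centers = centers, window = window, bin = bin,
            labels = labels, kind = if (is_trace) "trace" else "spikes",
            class = c("aligned_matrix", "matrix", "array"))
}

#' Condition-split trial averages
#'
#' Mean and across-trial standard error per time bin, split by a condition
#' label (e.g., reward size or target direction). Conditions with fewer than
#' 2 trials are excluded with a warning. For dopamine input, nulled bins are
#' excluded from the mean's denominator.
#'
#' @param mat an [align_to_events()] matrix.
#' @param split_by condition column name in the attached labels, or a vector
#'   of per-trial labels.
#' @return List of class `condition_average`: per condition, a list with
#'   `mean`, `se`, `n_trials`; plus `bin_centers`.
#' @export
condition_average <- function(mat, split_by) {
  labs <- attr(mat, "labels")
  cond <- if (is.character(split_by) && length(split_by) == 1L) {
    if (is.null(labs) || !split_by %in% names(labs))
      stop("no label column ", split_by)
    labs[[split_by]]
  } else split_by
  stopifnot(length(cond) == nrow(mat))
  out <- list()
  for (lv in unique(cond)) {
    m <- mat[cond == lv, , drop = FALSE]
    if (nrow(m) < 2L) {
      warning("condition ", lv, " has < 2 trials; excluded")
      next
    }
    n_eff <- colSums(!is.na(m))
    mu <- colMeans(m, na.rm = TRUE)
    se <- apply(m, 2L, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1L))
    out[[as.character(lv)]] <- list(mean = mu, se = se, n_trials = nrow(m))
  }
  structure(out, bin_centers = attr(mat, "bin_centers"),
            class = "condition_average")
}

#' @export
print.condition_average <- function(x, ...) {
  cat("<condition_average>\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d trials, grand mean %.3f\n", nm, x[[nm]]$n_trials,
                mean(x[[nm]]$mean, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.condition_average <- function(x, ylab = "mean", ...) {
  bc <- attr(x, "bin_centers")
  rng <- range(unlist(lapply(x, function(c) {
    ok <- is.finite(c$mean)
    c(c$mean[ok] - c$se[ok], c$mean[ok] + c$se[ok])
  })))
  graphics::plot(NA, xlim = range(bc), ylim = rng, xlab = "time (s)",
                 ylab = ylab, ...)
  cols <- grDevices::palette.colors(max(2L, length(x)))
  for (i in seq_along(x)) {
    c <- x[[i]]
    graphics::polygon(c(bc, rev(bc)),
                      c(c$mean - c$se, rev(c$mean + c$se)),
                      col = grDevices::adjustcolor(cols[i], 0.25), border = NA)
    graphics::lines(bc, c$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(x), col = cols[seq_along(x)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Permutation test for a condition difference in a time window
#'
#' Tests whether the across-trial mean of the window-averaged response
#' differs between two conditions, by permuting condition labels.
#'
#' @param mat an [align_to_events()] matrix.
#' @param cond two-level per-trial condition vector.
#' @param window `c(start, end)` in seconds relative to the event.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return List with `observed` (mean difference, first level minus second)
#'   and `p_value` (two-sided).
#' @export
perm_test_window <- function(mat, cond, window, n_perm = 1000, seed = 1) {
  bc <- attr(mat, "bin_centers")
  sel <- bc >= window[1] & bc <= window[2]
  v <- rowMeans(mat[, sel, drop = FALSE], na.rm = TRUE)
  lv <- unique(cond)
  stopifnot(length(lv) == 2L)
  obs <- mean(v[cond == lv[1L]], na.rm = TRUE) -
    mean(v[cond == lv[2L]], na.rm = TRUE)
  perm <- with_seed(seed, replicate(n_perm, {
    p <- sample(cond)
    mean(v[p == lv[1L]], na.rm = TRUE) - mean(v[p == lv[2L]], na.rm = TRUE)
  }))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  list(observed = obs, p_value = p)
}
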