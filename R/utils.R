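# Internal helpers: seeding, filtering, small numerics.

#' Derive a child seed from a master seed
#'
#' All stochastic generators in the package draw their seeds from a single
#' master seed through this deterministic mixing function, so that one integer
#' reproduces an entire synthetic session while keeping the per-component
#' streams distinct.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647 # 2^31 - 1, Mersenne prime (Park-Miller modulus)
  s <- (abs(master) %% m)
  s <- (s * 48271) %% m
  s <- (s + (index %% m) * 69621) %% m
  as.integer(s %% (m - 1L) + 1L)
}

# Evaluate `expr` under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Zero-phase band-pass (4 poles total: order-2 Butterworth applied
# forward-backward). Detection path only; the data path is never filtered.
bandpass_zp <- function(x, lo, hi, fs) {
  stopifnot(lo > 0, lo < hi, hi < fs / 2)
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase high-pass (4 poles total), detection path of the line-noise pass.
highpass_zp <- function(x, cutoff, fs) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bf, x))
}

# Causal (forward-only) Butterworth high-pass, the spike data path.
highpass_causal <- function(x, cutoff, fs, poles = 4L) {
  stopifnot(cutoff > 0, cutoff < fs / 2)
  bf <- signal::butter(poles, cutoff / (fs / 2), type = "high")
  as.numeric(signal::filter(bf, x))
}

# Robust SD about zero: median absolute amplitude / 0.6745.
robust_sd <- function(x) stats::median(abs(x)) / 0.6745

# Merge closed integer intervals given as a 2-column matrix [start, end].
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  out <- matrix(NA_integer_, nrow(iv), 2L)
  k <- 1L
  out[1L, ] <- iv[1L, ]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    if (iv[i, 1L] <= out[k, 2L] + 1L) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      k <- k + 1L
      out[k, ] <- iv[i, ]
    }
  }
  out[seq_len(k), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
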