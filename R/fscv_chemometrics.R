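# Dopamine concentration estimation from cyclic voltammograms:
# background subtraction, principal-component projection against analyte
# standards, and nulling of frames with excessive out-of-subspace residual
# (Q > Q_alpha) or movement-artifact correlation (r > 0.8).

#' Background-subtract a CV stream
#'
#' `dI[s] = frame[s] - frame[ref]`, removing the large non-faradaic current
#' common to all scans and isolating redox changes. The reference is usually
#' an alignment event (e.g., the target cue) so that all task-modulated
#' signals share a uniform baseline.
#'
#' @param stream a [gen_cv_stream()] object (`cv_stream`).
#' @param ref reference scan index (1-based), or a time in seconds when
#'   `as_time = TRUE` (nearest scan used).
#' @param as_time interpret `ref` as a time (default `FALSE`).
#' @return Matrix scans x points of current differences (nA), attribute
#'   `ref_index`.
#' @export
background_subtract <- function(stream, ref = 1L, as_time = FALSE) {
  stopifnot(inherits(stream, "cv_stream"))
  if (as_time) ref <- which.min(abs(stream$scan_times - ref))
  ref <- as.integer(ref)
  if (ref < 1L || ref > nrow(stream$frames))
    stop("reference scan outside the stream")
  di <- sweep(stream$frames, 2L, stream$frames[ref, ])
  attr(di, "ref_index") <- ref
  di
}

#' Fit an analyte standards library
#'
#' Builds the projection basis from labeled training voltammograms of
#' dopamine, pH, and movement artifact. One direction per analyte class is
#' taken from the class's leading singular vector; further pooled principal
#' components are appended until at least `var_target` of the training
#' variance is captured, and the set is orthonormalized. The dopamine
#' calibration (nM per unit DA score) is the least-squares slope of known
#' concentration on DA score, and `Q_alpha` is a quantile (default 95th
#' percentile) of the training residuals.
#'
#' @param cvs training CVs, rows = scans (background-subtracted, nA).
#' @param labels class label per row: `"DA"`, `"pH"`, `"movement"`.
#' @param concentrations known DA concentration per row, nM (`NA` for
#'   non-DA rows).
#' @param var_target retained training variance (default 0.99).
#' @param q_quantile quantile of training Q used for `Q_alpha`
#'   (default 0.95).
#' @param q_alpha explicit residual tolerance, overriding the quantile rule.
#' @return An object of class `standards_library`: orthonormal `basis`
#'   (points x k), index of the DA component, `calibration_nM`,
#'   `q_alpha`, and `movement_templates` (class-mean movement CVs used for
#'   the correlation screen).
#' @export
fit_standards <- function(cvs, labels, concentrations = NULL,
                          var_target = 0.99, q_quantile = 0.95,
                          q_alpha = NULL) {
  stopifnot(is.matrix(cvs), nrow(cvs) == length(labels))
  classes <- c("DA", "pH", "movement")
  for (cl in classes)
    if (sum(labels == cl) < 2L)
      stop("need at least 2 training CVs of class ", cl)
  if (is.null(concentrations))
    stop("known DA concentrations are required for calibration")
  # one leading direction per class (uncentered SVD: background-subtracted
  # CVs have a physical zero)
  dirs <- sapply(classes, function(cl) {
    m <- cvs[labels == cl, , drop = FALSE]
    sv <- svd(m, nu = 0L, nv = 1L)
    v <- sv$v[, 1L]
    # orient so that the class mean projects positively
    if (sum(colMeans(m) * v) < 0) v <- -v
    v
  })
  basis <- qr.Q(qr(dirs))
  # keep orientation of the QR columns aligned with the class directions
  for (j in seq_len(ncol(basis)))
    if (sum(basis[, j] * dirs[, j]) < 0) basis[, j] <- -basis[, j]
  # append pooled PCs until the variance target is met
  total_ss <- sum(cvs^2)
  resid <- cvs - cvs %*% basis %*% t(basis)
  if (total_ss > 0 && sum(resid^2) / total_ss > 1 - var_target) {
    sv <- svd(resid, nu = 0L)
    cum <- cumsum(sv$d^2)
    need <- which(1 - (sum(resid^2) - cum) / total_ss >= var_target)[1L]
    extra <- sv$v[, seq_len(min(need, ncol(sv$v))), drop = FALSE]
    basis <- qr.Q(qr(cbind(basis, extra)))[, seq_len(ncol(dirs) + need),
                                           drop = FALSE]
  }
  da_idx <- 1L # first column tracks the DA direction
  scores_da <- as.numeric(cvs %*% basis[, da_idx])
  known <- !is.na(concentrations) & labels == "DA"
  if (sum(known) < 2L) stop("need >= 2 DA rows with known concentrations")
  calib <- sum(concentrations[known] * scores_da[known]) /
    sum(scores_da[known]^2)
  qtrain <- rowSums((cvs - cvs %*% basis %*% t(basis))^2)
  if (is.null(q_alpha))
    q_alpha <- max(stats::quantile(qtrain, q_quantile), 1e-12)
  # movement screen uses the denoised class direction (leading singular
  # vector), not a raw row mean whose own noise would cap the attainable r
  mov_dir <- dirs[, "movement"] * sqrt(mean(rowSums(
    cvs[labels == "movement", , drop = FALSE]^2)))
  structure(list(basis = basis, da_index = da_idx,
                 calibration_nM = calib, q_alpha = q_alpha,
                 movement_templates = mov_dir,
                 points = ncol(cvs)),
            class = "standards_library")
}

#' @export
print.standards_library <- function(x, ...) {
  cat(sprintf(
    "<standards_library> %d components over %d points; calibration %.4g nM/score; Q_alpha %.4g\n",
    ncol(x$basis), x$points, x$calibration_nM, x$q_alpha))
  invisible(x)
}

#' Project background-subtracted CVs onto the standards and null bad scans
#'
#' Per scan: component scores by projection onto the standards basis;
#' `delta_da = DA score x calibration`; `Q` = squared residual norm outside
#' the component subspace. Scans with `Q > Q_alpha` are nulled (reason
#' `Q_exceeded`); scans whose dI correlates with any movement template at
#' `r > r_null` are nulled (reason `movement_corr`).
#'
#' @param di scans x points matrix from [background_subtract()].
#' @param lib a [fit_standards()] library.
#' @param scan_times scan times, s (default 100 ms spacing).
#' @param r_null movement-correlation nulling threshold (default 0.8).
#' @return A `da_trace` data frame: `time_s`, `delta_da` (nM; `NA` when
#'   nulled), `q`, `null_reason` in `none`/`Q_exceeded`/`movement_corr`.
#' @export
project_cvs <- function(di, lib, scan_times = NULL, r_null = 0.8) {
  stopifnot(inherits(lib, "standards_library"))
  if (is.vector(di)) di <- matrix(di, nrow = 1L)
  if (ncol(di) != lib$points)
    stop("point count (", ncol(di), ") does not match library (", lib$points, ")")
  n <- nrow(di)
  if (is.null(scan_times)) scan_times <- (seq_len(n) - 1L) * 0.1
  scores <- di %*% lib$basis
  recon <- scores %*% t(lib$basis)
  q <- rowSums((di - recon)^2)
  delta <- scores[, lib$da_index] * lib$calibration_nM
  mov <- lib$movement_templates
  if (is.vector(mov)) mov <- matrix(mov, nrow = 1L)
  rmax <- apply(di, 1L, function(x) {
    if (stats::sd(x) == 0) return(0)
    max(apply(mov, 1L, function(m) suppressWarnings(stats::cor(x, m))), na.rm = TRUE)
  })
  reason <- rep("none", n)
  reason[q > lib$q_alpha] <- "Q_exceeded"
  reason[rmax > r_null] <- "movement_corr"
  delta[reason != "none"] <- NA_real_
  out <- data.frame(time_s = scan_times, delta_da = delta, q = q,
                    null_reason = reason)
  class(out) <- c("da_trace", "data.frame")
  out
}

#' @export
print.da_trace <- function(x, ...) {
  nn <- table(factor(x$null_reason,
                     levels = c("none", "Q_exceeded", "movement_corr")))
  cat(sprintf("<da_trace> %d scans: %d valid, %d Q-nulled, %d movement-nulled\n",
              nrow(x), nn[["none"]], nn[["Q_exceeded"]], nn[["movement_corr"]]))
  NextMethod()
}

#' Color-plot matrix for background-subtracted currents
#'
#' Deterministic reshaping: applied scan voltage on the rows (y-axis), scan
#' time on the columns (x-axis), current difference as value. No values are
#' modified.
#'
#' @param di scans x points matrix from [background_subtract()].
#' @param stream the originating `cv_stream` (for axes).
#' @return Matrix points x scans with `voltage` and `time_s` attributes.
#' @export
color_plot_matrix <- function(di, stream) {
  m <- t(di)
  attr(m, "voltage") <- stream$voltage_axis
  attr(m, "time_s") <- stream$scan_times
  m
}

#' @export
plot.cv_stream <- function(x, ref = 1L, ...) {
  di <- background_subtract(x, ref)
  m <- color_plot_matrix(di, x)
  graphics::image(x = attr(m, "time_s"), y = seq_len(nrow(m)), z = t(m),
                  xlab = "time (s)", ylab = "scan point (-0.4 -> 1.3 -> -0.4 V)",
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE), ...)
  invisible(m)
}
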