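# Theta phase assignment, track linearization and phase-precession fitting.

#' Assign theta phases to spikes
#'
#' Phase is linearly interpolated between consecutive theta peaks:
#' `360 * (t - peak_before) / (peak_after - peak_before)` degrees. Spikes
#' outside the peak span are dropped (their count is reported).
#'
#' @param spikes spike times, seconds.
#' @param theta_peaks theta-peak times, seconds (>= 2, increasing).
#' @return list with `phase_deg` (per retained spike), `spike_times`
#'   (retained), `n_dropped`.
#' @export
assign_theta_phase <- function(spikes, theta_peaks) {
  if (length(theta_peaks) < 2) abort("need at least 2 theta peaks")
  if (any(diff(theta_peaks) <= 0)) abort("theta peaks must be increasing")
  inside <- spikes >= theta_peaks[1] & spikes <= theta_peaks[length(theta_peaks)]
  s <- spikes[inside]
  k <- findInterval(s, theta_peaks, rightmost.closed = TRUE)
  k[k == length(theta_peaks)] <- length(theta_peaks) - 1L
  ph <- 360 * (s - theta_peaks[k]) / (theta_peaks[k + 1L] - theta_peaks[k])
  list(phase_deg = wrap_deg(ph), spike_times = s,
       n_dropped = sum(!inside))
}

#' Linearize positions on a circular track
#'
#' Converts 2D positions around a track centre into degrees on the track:
#' the polar angle relative to `ref_deg`, unwrapped so consecutive samples
#' never jump by more than half a turn (laps accumulate past 360).
#'
#' @param positions n x 2 matrix of (x, y) canvas positions, cm.
#' @param center track centre c(x, y), cm.
#' @param ref_deg direction mapped to 0 degrees (default due east).
#' @return numeric unwrapped track position, degrees; samples at the centre
#'   are NA (flagged with a warning).
#' @export
linearize_circular <- function(positions, center, ref_deg = 0) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 2)
  dx <- positions[, 1] - center[1]; dy <- positions[, 2] - center[2]
  at_center <- dx == 0 & dy == 0
  if (any(at_center, na.rm = TRUE))
    warning("position(s) at the track centre cannot be linearized")
  ang <- atan2(dy, dx) * 180 / pi - ref_deg
  ang[at_center] <- NA_real_
  # unwrap: accumulate the smallest signed step between consecutive samples
  n <- length(ang)
  if (n <= 1) return(wrap_deg(ang))
  steps <- ang_diff_deg(ang[-1], ang[-n])
  out <- cumsum(c(wrap_deg(ang[1]), ifelse(is.na(steps), 0, steps)))
  out[is.na(ang)] <- NA_real_
  out
}

#' Fit a line to theta phase versus position
#'
#' Least-squares regression of spike phase (degrees) on linearized spike
#' position. For each spike, `d_p` is the position implied by inverting the
#' fitted line at the spike's phase minus the actual position; the unbiased
#' variance of `d_p` measures the tightness of phase precession. Fits with
#' near-zero slope cannot be inverted and are returned with
#' `degenerate = TRUE` and `d_p_variance = NA`.
#'
#' @param phases spike theta phases, degrees.
#' @param positions linearized spike positions (same length, >= 3 distinct).
#' @param slope_tol |slope| below which the inversion is declared
#'   degenerate, degrees per position unit.
#' @return object of class `phase_precession_fit`: list with `slope`,
#'   `intercept`, `d_p`, `d_p_variance`, `degenerate`, `n`.
#' @export
fit_phase_precession <- function(phases, positions, slope_tol = 1e-6) {
  ok <- is.finite(phases) & is.finite(positions)
  phases <- phases[ok]; positions <- positions[ok]
  if (length(phases) < 3) abort("need at least 3 spikes to fit phase precession")
  if (stats::sd(positions) == 0) abort("zero spread in spike positions")
  fit <- stats::lm.fit(cbind(1, positions), phases)
  intercept <- fit$coefficients[1]; slope <- fit$coefficients[2]
  degenerate <- !is.finite(slope) || abs(slope) < slope_tol
  if (degenerate) {
    d_p <- rep(NA_real_, length(phases))
    v <- NA_real_
  } else {
    d_p <- (phases - intercept) / slope - positions
    v <- stats::var(d_p)
  }
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 phases = phases, positions = positions,
                 d_p = d_p, d_p_variance = v,
                 degenerate = degenerate, n = length(phases)),
            class = "phase_precession_fit")
}

#' @export
print.phase_precession_fit <- function(x, ...) {
  cat(sprintf("<phase_precession_fit> n = %d, slope %.3f deg/unit, var(d_p) %s\n",
              x$n, x$slope,
              if (x$degenerate) "NA (degenerate slope)" else sprintf("%.2f", x$d_p_variance)))
  invisible(x)
}
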