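# Head-direction tuning curves.

#' Head-direction tuning curve
#'
#' Spike counts per 5-degree head-direction bin divided by the time spent
#' facing that bin, smoothed with a circular (wrap-around) Gaussian. Peak
#' rate and full width at half maximum (by linear interpolation at half peak
#' on both flanks) are computed on the smoothed curve.
#'
#' @param session a [tracked_session()] with head direction.
#' @param spikes spike times, seconds.
#' @param bin_width angular bin width, degrees (72 bins at the default 5).
#' @param sigma Gaussian smoothing SD, bins.
#' @param speed_min minimum running speed, cm/s (0 keeps all samples).
#' @return object of class `tuning_curve`: list with `bin_centers_deg`,
#'   `occupancy_s`, `spike_counts`, `rate_hz` (unsmoothed),
#'   `rate_smoothed_hz`, `peak_rate_hz`, `peak_deg`, `fwhm_deg` (NA when the
#'   curve never falls below half peak).
#' @export
hd_tuning <- function(session, spikes, bin_width = 5, sigma = 1.25,
                      speed_min = 2) {
  t <- session$time_s
  hd <- session$hd_deg
  ok <- !is.na(hd) & !is.na(session$speed_cms) & session$speed_cms >= speed_min
  if (!any(ok)) abort("no samples with defined head direction survive the filter")
  n_bins <- round(360 / bin_width)
  dwell <- c(diff(t), stats::median(diff(t)))
  bin <- floor(wrap_deg(hd) / bin_width) + 1L
  bin[bin > n_bins] <- n_bins
  occ <- numeric(n_bins)
  acc <- tapply(dwell[ok], bin[ok], sum)
  occ[as.integer(names(acc))] <- acc
  si <- nearest_index(t, spikes)
  s_ok <- ok[si]
  cnt <- numeric(n_bins)
  if (any(s_ok)) {
    acc <- tapply(rep(1, sum(s_ok)), bin[si[s_ok]], sum)
    cnt[as.integer(names(acc))] <- acc
  }
  rate <- ifelse(occ > 0, cnt / occ, NA_real_)
  sm <- circular_smooth(rate, sigma)
  peak_i <- which.max(sm)
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  structure(list(bin_centers_deg = centers, occupancy_s = occ,
                 spike_counts = cnt, rate_hz = rate, rate_smoothed_hz = sm,
                 peak_rate_hz = sm[peak_i], peak_deg = centers[peak_i],
                 fwhm_deg = tuning_fwhm(sm, bin_width, peak_i)),
            class = "tuning_curve")
}

#' Circular mask-normalized Gaussian smoothing of an angular curve
#' @noRd
circular_smooth <- function(rate, sigma) {
  n <- length(rate)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) / 2L
  v <- ifelse(is.na(rate), 0, rate)
  m <- as.numeric(!is.na(rate))
  num <- numeric(n); den <- numeric(n)
  for (off in -r:r) {
    idx <- ((seq_len(n) - 1L + off) %% n) + 1L
    w <- k[off + r + 1L]
    num <- num + w * v[idx]
    den <- den + w * m[idx]
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Full width at half maximum on a circular curve
#' @noRd
tuning_fwhm <- function(sm, bin_width, peak_i) {
  n <- length(sm)
  peak <- sm[peak_i]
  if (!is.finite(peak) || peak <= 0) return(NA_real_)
  half <- peak / 2
  v <- sm
  v[is.na(v)] <- 0
  walk <- function(dir) {
    # steps (in bins, possibly fractional) from the peak to the half-maximum
    # crossing in direction dir
    for (s in seq_len(n - 1L)) {
      i0 <- ((peak_i - 1L + dir * (s - 1L)) %% n) + 1L
      i1 <- ((peak_i - 1L + dir * s) %% n) + 1L
      if (v[i1] <= half) {
        frac <- if (v[i0] == v[i1]) 0 else (v[i0] - half) / (v[i0] - v[i1])
        return((s - 1L) + frac)
      }
    }
    NA_real_ # never falls below half: width undefined
  }
  up <- walk(1L); down <- walk(-1L)
  if (is.na(up) || is.na(down)) return(NA_real_)
  (up + down) * bin_width
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> peak %.2f Hz at %.0f deg, fwhm %s deg\n",
              x$peak_rate_hz, x$peak_deg,
              if (is.na(x$fwhm_deg)) "NA" else sprintf("%.1f", x$fwhm_deg)))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$bin_centers_deg, x$rate_smoothed_hz, type = "l",
                 xlab = "head direction (deg)", ylab = "firing rate (Hz)", ...)
  invisible(x)
}
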