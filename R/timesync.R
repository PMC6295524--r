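# Clock synchronization and interframe-interval (IFI) diagnostics.
#
# Each camera computer logs frame timestamps on its own device clock, and a
# shared TTL pulse train is logged both on the device and on the neural data
# acquisition (DAQ) system. Pairing TTL transitions by index gives a map from
# the device clock to the acquisition clock: the first on-transition gives the
# instantaneous offset, later transitions correct drift.

#' Per-camera frame timestamp series
#'
#' @param times frame timestamps, seconds, strictly increasing.
#' @param rate nominal frame rate, Hz (expected IFI = 1/rate).
#' @param camera camera identifier.
#' @return object of class `frame_timestamp_series`.
#' @export
frame_timestamp_series <- function(times, rate, camera = 1L) {
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    abort("frame timestamps must be strictly increasing")
  if (!is_scalar_num(rate) || rate <= 0) abort("nominal rate must be > 0")
  structure(list(camera = camera, times = times, rate = rate),
            class = "frame_timestamp_series")
}

#' @export
print.frame_timestamp_series <- function(x, ...) {
  cat(sprintf("<frame_timestamp_series> camera %s: %d frames @ %g Hz nominal\n",
              format(x$camera), length(x$times), x$rate))
  invisible(x)
}

#' Build a device-to-acquisition clock map from paired TTL logs
#'
#' Transitions are paired by index (both devices see the same physical pulse
#' train). If the logs have unequal lengths they are truncated to the common
#' prefix with a warning; non-alternating state sequences also warn.
#'
#' @param device_ttl,daq_ttl data.frames with columns `state` (0/1) and
#'   `time_s`, one row per TTL transition, as logged on the camera device and
#'   the acquisition system respectively.
#' @return object of class `clock_map`: data.frame with `device_time_s`,
#'   `acq_time_s` and `offset_s` (device minus acquisition) per transition.
#' @export
build_clock_map <- function(device_ttl, daq_ttl) {
  for (log in list(device_ttl, daq_ttl)) {
    if (!is.data.frame(log) || nrow(log) == 0)
      abort("TTL logs must be nonempty data.frames")
    if (!all(c("state", "time_s") %in% names(log)))
      abort("TTL logs need columns 'state' and 'time_s'")
  }
  n <- min(nrow(device_ttl), nrow(daq_ttl))
  if (nrow(device_ttl) != nrow(daq_ttl))
    warning(sprintf("TTL logs differ in length (%d vs %d); using common prefix of %d",
                    nrow(device_ttl), nrow(daq_ttl), n))
  dev <- device_ttl[seq_len(n), ]
  daq <- daq_ttl[seq_len(n), ]
  for (s in list(dev$state, daq$state)) {
    if (n > 1 && any(diff(s) == 0))
      warning("TTL state sequence does not alternate; check the logs")
  }
  if (any(diff(dev$time_s) <= 0) || any(diff(daq$time_s) <= 0))
    abort("TTL transition times must be strictly increasing")
  map <- data.frame(device_time_s = dev$time_s,
                    acq_time_s = daq$time_s,
                    offset_s = dev$time_s - daq$time_s)
  class(map) <- c("clock_map", "data.frame")
  map
}

#' Align frame timestamps to the acquisition clock
#'
#' Piecewise-linear interpolation between TTL pairs maps device time to
#' acquisition time; this is exact whenever the device clock is an affine
#' function of the acquisition clock and at least two TTL pairs exist.
#' Outside the TTL-covered interval the nearest pair's constant offset is
#' used. With a single pair only that offset correction is possible.
#'
#' @param frames a [frame_timestamp_series()] on the device clock.
#' @param map a [build_clock_map()] result.
#' @return a `frame_timestamp_series` on the acquisition clock.
#' @export
align_timestamps <- function(frames, map) {
  stopifnot(inherits(frames, "frame_timestamp_series"), inherits(map, "clock_map"))
  t <- frames$times
  if (nrow(map) == 1L) {
    aligned <- t - map$offset_s[1]
  } else {
    aligned <- stats::approx(map$device_time_s, map$acq_time_s, xout = t,
                             rule = 1)$y
    lo <- t < map$device_time_s[1]
    hi <- t > map$device_time_s[nrow(map)]
    aligned[lo] <- t[lo] - map$offset_s[1]
    aligned[hi] <- t[hi] - map$offset_s[nrow(map)]
  }
  frame_timestamp_series(aligned, frames$rate, frames$camera)
}

#' Interframe-interval jitter report
#'
#' Deviations are `IFI_i - 1/rate`. Jitter is reported as the range (min, max)
#' of deviation over the session. An IFI within +/-25% of k times the expected
#' IFI (integer k >= 2) is counted as k - 1 dropped frames, separating genuine
#' frame loss from timing jitter.
#'
#' @param frames a [frame_timestamp_series()] with >= 2 frames.
#' @param thresholds deviation magnitudes (seconds) at which to report the
#'   fraction of IFIs exceeding each; default 1 ms and 7 ms.
#' @return object of class `jitter_report`: list with `expected_ifi_s`,
#'   `deviations_s`, `jitter_range_s` (min, max), `dropped_frames`,
#'   `exceed_fraction` (named by threshold) and `n_frames`.
#' @export
ifi_report <- function(frames, thresholds = c(0.001, 0.007)) {
  stopifnot(inherits(frames, "frame_timestamp_series"))
  if (length(frames$times) < 2) abort("ifi_report needs at least 2 frames")
  expected <- 1 / frames$rate
  ifi <- diff(frames$times)
  k <- round(ifi / expected)
  is_drop <- k >= 2 & abs(ifi - k * expected) <= 0.25 * k * expected
  dropped <- sum(pmax(k[is_drop] - 1, 0))
  dev <- ifi - expected
  exceed <- vapply(thresholds, function(th) mean(abs(dev) > th), numeric(1))
  names(exceed) <- sprintf("gt_%gms", thresholds * 1000)
  structure(list(
    camera = frames$camera,
    expected_ifi_s = expected,
    deviations_s = dev,
    jitter_range_s = c(min = min(dev), max = max(dev)),
    dropped_frames = as.integer(dropped),
    exceed_fraction = exceed,
    n_frames = length(frames$times)
  ), class = "jitter_report")
}

#' @export
print.jitter_report <- function(x, ...) {
  cat(sprintf(
    "<jitter_report> camera %s: %d frames, expected IFI %.6f s\n  jitter range [%+.4f, %+.4f] ms, %d dropped frame(s)\n",
    format(x$camera), x$n_frames, x$expected_ifi_s,
    x$jitter_range_s[1] * 1000, x$jitter_range_s[2] * 1000, x$dropped_frames))
  invisible(x)
}

#' Inject timing jitter by resampling interframe intervals
#'
#' Replaces the observed IFIs with IFIs drawn with replacement from `ifi_pool`
#' (e.g. the interval distribution of a noisier camera), rescaled so the
#' jittered session spans exactly the original session. Frame count is
#' conserved and the first timestamp is kept.
#'
#' @param frames a [frame_timestamp_series()].
#' @param ifi_pool nonempty numeric pool of intervals, seconds.
#' @param seed integer seed.
#' @return a `frame_timestamp_series` with jittered times.
#' @export
inject_jitter <- function(frames, ifi_pool, seed) {
  stopifnot(inherits(frames, "frame_timestamp_series"))
  if (length(ifi_pool) == 0) abort("ifi_pool must be nonempty")
  n <- length(frames$times)
  if (n < 2) return(frames)
  span <- frames$times[n] - frames$times[1]
  with_local_seed(seed, {
    ifis <- sample(ifi_pool, n - 1L, replace = TRUE)
    ifis <- ifis * (span / sum(ifis))
    frame_timestamp_series(frames$times[1] + c(0, cumsum(ifis)),
                           frames$rate, frames$camera)
  })
}

#' Inter-camera frame timing differences
#'
#' With all cameras aligned to the acquisition clock, the camera with the
#' earliest first frame is the reference; for each frame index in the common
#' prefix, the timing difference of every camera relative to the reference is
#' reported, together with each camera's start lag.
#'
#' @param series_list list of aligned [frame_timestamp_series()] (>= 2).
#' @return list with `reference` (camera id), `start_lag_s` (named numeric),
#'   `differences_s` (matrix frames x cameras), `truncated_to` (common frame
#'   count) and `max_abs_difference_s`.
#' @export
intercamera_lag_report <- function(series_list) {
  if (length(series_list) < 2) abort("need at least 2 cameras")
  starts <- vapply(series_list, function(s) s$times[1], numeric(1))
  ids <- vapply(series_list, function(s) format(s$camera), character(1))
  ref <- which.min(starts)
  n <- min(vapply(series_list, function(s) length(s$times), integer(1)))
  counts <- vapply(series_list, function(s) length(s$times), integer(1))
  truncated <- any(counts != n)
  if (truncated)
    warning(sprintf("unequal frame counts; comparing common prefix of %d frames", n))
  tref <- series_list[[ref]]$times[seq_len(n)]
  diffs <- vapply(series_list,
                  function(s) s$times[seq_len(n)] - tref, numeric(n))
  colnames(diffs) <- ids
  lags <- starts - starts[ref]
  names(lags) <- ids
  list(reference = series_list[[ref]]$camera,
       start_lag_s = lags,
       differences_s = diffs,
       truncated_to = n,
       max_abs_difference_s = max(abs(diffs)))
}

#' Serialize a jitter report
#'
#' Writes per-IFI deviations as CSV and the summary as JSON.
#' @param report a `jitter_report`.
#' @param csv_path,json_path output paths (either may be NULL to skip).
#' @return invisibly, the summary list written to JSON.
#' @export
write_jitter_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "jitter_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(ifi_index = seq_along(report$deviations_s),
                                deviation_s = report$deviations_s),
                     csv_path, row.names = FALSE)
  }
  summary <- list(camera = format(report$camera),
                  expected_ifi_s = report$expected_ifi_s,
                  jitter_min_s = unname(report$jitter_range_s[1]),
                  jitter_max_s = unname(report$jitter_range_s[2]),
                  dropped_frames = report$dropped_frames,
                  exceed_fraction = as.list(report$exceed_fraction),
                  n_frames = report$n_frames)
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
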