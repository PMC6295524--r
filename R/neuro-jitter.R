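# Frame-timing jitter degradation experiment: compare spatial-coding metrics
# computed with the native frame timestamps against the same data scored
# with jittered frame-time estimates. The entire effect operates through the
# assignment of positions to spike times, so spike trains and true positions
# are untouched; only the believed frame times change.

#' Spatial-coding metrics for one cell
#'
#' Spatial information from the adaptive-binned map, peak firing rate from
#' the Gaussian-smoothed map, and the size (bins) of the largest place field.
#'
#' @param session a [tracked_session()].
#' @param spikes spike times, seconds.
#' @param bin_size spatial bin side, cm.
#' @param sigma smoothing SD, bins.
#' @param alpha adaptive-binning constant.
#' @param speed_min,occ_min as in [compute_rate_map()].
#' @param bounds optional map bounds (keep fixed across conditions).
#' @return list with `spatial_information`, `peak_rate`, `field_size`,
#'   `n_spikes_used`.
#' @export
cell_metrics <- function(session, spikes, bin_size = 2, sigma = 1.25,
                         alpha = 1e6, speed_min = 2, occ_min = 0.4,
                         bounds = NULL) {
  raw <- compute_rate_map(session, spikes, bin_size, speed_min, occ_min, bounds)
  sm <- smooth_map_gaussian(raw, sigma)
  fields <- detect_place_fields(sm)
  info <- spatial_information(adaptive_smooth(raw, session, alpha))
  list(spatial_information = info,
       peak_rate = sm$peak_rate,
       field_size = if (length(fields)) fields[[1]]$size else 0L,
       n_spikes_used = raw$n_spikes_used)
}

#' Jitter degradation experiment
#'
#' For each cell, computes [cell_metrics()] once with the session's native
#' frame timestamps and once with timestamps whose interframe intervals were
#' resampled from `ifi_pool` (via [inject_jitter()]); spike-to-position
#' assignment then uses the jittered times. Paired Wilcoxon signed rank
#' tests compare the two conditions per metric when at least `min_cells`
#' cells are available.
#'
#' Cells with fewer than `min_spikes` spikes or mean rate above
#' `max_mean_rate` Hz (putative interneurons) are dropped; when
#' `p_values` is supplied, cells with `p >= 0.01` are dropped too.
#'
#' @param session a [tracked_session()].
#' @param cells list of spike-time vectors (or `spike_train`s).
#' @param ifi_pool IFI pool, seconds, e.g. [commercial_ifi_pool()].
#' @param seed integer seed (drives the IFI resampling).
#' @param bin_size spatial bin side, cm.
#' @param min_spikes,max_mean_rate cell inclusion criteria.
#' @param p_values optional per-cell spatial-information shuffle p-values.
#' @param min_cells minimum cells for the paired tests.
#' @param ... passed to [cell_metrics()].
#' @return list with `metrics` (data.frame of per-cell paired metrics),
#'   `tests` (per-metric [wilcoxon_signed_rank()] results, or NULL when
#'   fewer than `min_cells` cells), `n_cells`, `dropped`.
#' @export
jitter_degradation_experiment <- function(session, cells, ifi_pool, seed = 1,
                                          bin_size = 2, min_spikes = 50,
                                          max_mean_rate = 10,
                                          p_values = NULL, min_cells = 6, ...) {
  spikes_of <- function(cell) if (inherits(cell, "spike_train")) cell$times else cell
  t <- session$time_s
  span <- t[length(t)] - t[1]
  keep <- vapply(seq_along(cells), function(i) {
    s <- spikes_of(cells[[i]])
    ok <- length(s) >= min_spikes && length(s) / span <= max_mean_rate
    if (!is.null(p_values)) ok <- ok && p_values[i] < 0.01
    ok
  }, logical(1))
  dropped <- which(!keep)
  cells <- cells[keep]
  if (!length(cells)) abort("no cell passes the inclusion criteria")
  rate <- 1 / stats::median(diff(t))
  native_ts <- frame_timestamp_series(t, rate)
  jit_ts <- inject_jitter(native_ts, ifi_pool, seed = seed)
  jit_session <- session
  jit_session$time_s <- jit_ts$times
  jit_session$speed_cms <- compute_speed(jit_ts$times, session$x_cm, session$y_cm)
  # shared bounds so bin grids match across conditions
  okp <- !is.na(session$x_cm)
  bounds <- c(min(session$x_cm[okp]), max(session$x_cm[okp]),
              min(session$y_cm[okp]), max(session$y_cm[okp]))
  rows <- lapply(seq_along(cells), function(i) {
    s <- spikes_of(cells[[i]])
    nat <- cell_metrics(session, s, bin_size, bounds = bounds, ...)
    jit <- cell_metrics(jit_session, s, bin_size, bounds = bounds, ...)
    data.frame(cell = i,
               native_info = nat$spatial_information,
               jittered_info = jit$spatial_information,
               native_peak = nat$peak_rate,
               jittered_peak = jit$peak_rate,
               native_field = nat$field_size,
               jittered_field = jit$field_size)
  })
  metrics <- do.call(rbind, rows)
  tests <- NULL
  if (nrow(metrics) >= min_cells) {
    tests <- list(
      spatial_information = wilcoxon_signed_rank(metrics$native_info,
                                                 metrics$jittered_info),
      peak_rate = wilcoxon_signed_rank(metrics$native_peak,
                                       metrics$jittered_peak),
      field_size = wilcoxon_signed_rank(metrics$native_field,
                                        metrics$jittered_field))
  }
  list(metrics = metrics, tests = tests, n_cells = nrow(metrics),
       dropped = dropped)
}
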