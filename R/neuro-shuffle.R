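# Cyclic-shift shuffle test for the significance of spatial information.

#' Shuffle test for spatial information
#'
#' The spike train is shifted cyclically against the position data
#' `n_shuffles` times by a uniform random offset in
#' `[margin, T - margin]` (T = session span), and the information score is
#' recomputed for each shift. The p-value is the fraction of shuffled scores
#' greater than or equal to the observed score; `p < 0.01` is the
#' conventional significance threshold.
#'
#' The `"raw"` method scores information on the unsmoothed binned map (fast,
#' fully vectorized across shuffles); `"adaptive"` recomputes the
#' adaptive-binned map per shuffle (slower, matches the map type used for
#' reporting observed scores).
#'
#' @param session a [tracked_session()].
#' @param spikes spike times, seconds.
#' @param bin_size spatial bin side, cm.
#' @param n_shuffles number of cyclic shifts (>= 1).
#' @param margin minimum shift, seconds.
#' @param seed integer seed.
#' @param method map estimator used for scoring (see details).
#' @param speed_min,occ_min as in [compute_rate_map()].
#' @param alpha adaptive-binning constant (adaptive method only).
#' @return list with `observed` (bits/spike), `null` (numeric vector),
#'   `p_value`, `significant` (p < 0.01), `n_shuffles`.
#' @export
shuffle_significance <- function(session, spikes, bin_size = 2,
                                 n_shuffles = 1000, margin = 30, seed = 1,
                                 method = c("raw", "adaptive"),
                                 speed_min = 2, occ_min = 0.4, alpha = 1e6) {
  method <- match.arg(method)
  if (n_shuffles < 1) abort("n_shuffles must be >= 1")
  t <- session$time_s
  T_span <- t[length(t)] - t[1]
  if (T_span <= 2 * margin)
    abort(sprintf("session span (%.1f s) must exceed twice the margin (%g s)", T_span, margin))
  base <- compute_rate_map(session, spikes, bin_size, speed_min, occ_min)
  with_local_seed(seed, {
    shifts <- stats::runif(n_shuffles, margin, T_span - margin)
    if (method == "adaptive") {
      obs <- spatial_information(adaptive_smooth(base, session, alpha))
      null <- vapply(shifts, function(sh) {
        sp2 <- t[1] + ((spikes - t[1] + sh) %% T_span)
        m <- compute_rate_map(session, sp2, bin_size, speed_min, occ_min)
        spatial_information(adaptive_smooth(m, session, alpha))
      }, numeric(1))
    } else {
      obs <- spatial_information(base)
      null <- shuffle_null_raw(session, spikes, base, shifts,
                               bin_size, speed_min)
    }
    p <- mean(null >= obs)
    list(observed = obs, null = null, p_value = p,
         significant = is.finite(p) && p < 0.01, n_shuffles = n_shuffles)
  })
}

#' Vectorized raw-map information null distribution
#' @noRd
shuffle_null_raw <- function(session, spikes, base, shifts, bin_size, speed_min) {
  t <- session$time_s
  T_span <- t[length(t)] - t[1]
  nx <- nrow(base$rate)
  x_edges <- base$x_edges; y_edges <- base$y_edges
  ok <- !is.na(session$x_cm) & !is.na(session$y_cm) &
    !is.na(session$speed_cms) & session$speed_cms >= speed_min
  ix <- findInterval(session$x_cm, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(session$y_cm, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  bin_of_sample <- ix + (iy - 1L) * nx
  vbins <- which(base$valid)
  occ <- base$occupancy[vbins]
  p_occ <- occ / sum(occ)
  bin_pos <- match(bin_of_sample, vbins) # NA for samples in invalid bins
  n_s <- length(spikes); n_sh <- length(shifts)
  if (n_s == 0) return(rep(NA_real_, n_sh))
  all_t <- t[1] + ((rep(spikes, times = n_sh) +
                      rep(shifts, each = n_s) - t[1]) %% T_span)
  si <- nearest_index(t, all_t)
  keep <- ok[si] & !is.na(bin_pos[si])
  sh_id <- rep(seq_len(n_sh), each = n_s)
  code <- bin_pos[si[keep]] + (sh_id[keep] - 1L) * length(vbins)
  counts <- matrix(tabulate(code, length(vbins) * n_sh), length(vbins), n_sh)
  rate <- counts / occ
  mean_rate <- colSums(p_occ * rate)
  ratio <- sweep(rate, 2, mean_rate, "/")
  terms <- p_occ * ratio * log2(ratio)
  terms[!is.finite(terms) | counts == 0] <- 0
  info <- colSums(terms)
  info[mean_rate <= 0] <- NA_real_
  info
}
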