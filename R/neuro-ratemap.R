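# Spatial firing-rate maps: occupancy- and speed-filtered binning, Gaussian
# smoothing with mask normalization, adaptive binning, Skaggs spatial
# information and place-field segmentation.
#
# Map matrices are indexed [ix, iy]: first dimension runs along x, second
# along y, with bin 1 at the lower spatial corner.

#' Spatial firing rate map
#'
#' Each tracked sample contributes its dwell time to its spatial bin and each
#' spike is assigned the position of the nearest tracked sample in time.
#' Samples (and their spikes) during which the animal moved slower than
#' `speed_min` are excluded; bins with less than `occ_min` seconds of
#' filtered occupancy are invalidated.
#'
#' @param session a [tracked_session()] (times on the same clock as spikes).
#' @param spikes spike times, seconds.
#' @param bin_size spatial bin side, cm (4 for large rooms, 2 otherwise).
#' @param speed_min minimum running speed, cm/s.
#' @param occ_min minimum occupancy per bin, seconds.
#' @param bounds c(xmin, xmax, ymin, ymax) cm; default snug around the data.
#' @return object of class `rate_map`: list with `bin_size`, `x_edges`,
#'   `y_edges`, `occupancy` (s), `spikes` (counts), `rate` (Hz, NA on
#'   invalid bins), `valid` (logical), `n_spikes_used`, `mean_rate`.
#' @export
compute_rate_map <- function(session, spikes, bin_size,
                             speed_min = 2, occ_min = 0.4, bounds = NULL) {
  stopifnot(inherits(session, "data.frame"))
  t <- session$time_s; x <- session$x_cm; y <- session$y_cm
  sp <- session$speed_cms
  ok <- !is.na(x) & !is.na(y) & !is.na(sp) & sp >= speed_min
  if (!any(ok)) abort("no tracked samples survive the speed filter")
  if (is.null(bounds)) {
    bounds <- c(min(x[ok]), max(x[ok]), min(y[ok]), max(y[ok]))
  }
  x_edges <- seq(bounds[1], bounds[2] + bin_size, by = bin_size)
  y_edges <- seq(bounds[3], bounds[4] + bin_size, by = bin_size)
  nx <- length(x_edges) - 1L; ny <- length(y_edges) - 1L
  dwell <- c(diff(t), stats::median(diff(t)))
  ix <- findInterval(x, x_edges, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, y_edges, rightmost.closed = TRUE, all.inside = TRUE)
  bin <- ix + (iy - 1L) * nx
  occ <- matrix(0, nx, ny)
  occ_acc <- tapply(dwell[ok], bin[ok], sum)
  occ[as.integer(names(occ_acc))] <- occ_acc
  # spikes -> nearest tracked sample
  si <- nearest_index(t, spikes)
  s_ok <- ok[si]
  cnt <- matrix(0, nx, ny)
  if (any(s_ok)) {
    cnt_acc <- tapply(rep(1, sum(s_ok)), bin[si[s_ok]], sum)
    cnt[as.integer(names(cnt_acc))] <- cnt_acc
  }
  # tolerance: at a regular frame rate, occupancy sums land exactly on the
  # threshold (e.g. 12 x 1/30 s = 0.4 s) and must not flip on roundoff
  valid <- occ >= occ_min - 1e-9
  if (!any(valid)) abort("no spatial bin reaches the minimum occupancy")
  rate <- matrix(NA_real_, nx, ny)
  rate[valid] <- cnt[valid] / occ[valid]
  structure(list(bin_size = bin_size, x_edges = x_edges, y_edges = y_edges,
                 occupancy = occ, spikes = cnt, rate = rate, valid = valid,
                 n_spikes_used = sum(cnt[valid]),
                 mean_rate = sum(cnt[valid]) / sum(occ[valid])),
            class = "rate_map")
}

#' @noRd
nearest_index <- function(sorted_times, query) {
  idx <- findInterval(query, sorted_times)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(sorted_times))
  ifelse(abs(sorted_times[hi] - query) < abs(sorted_times[lo] - query), hi, lo)
}

#' @export
print.rate_map <- function(x, ...) {
  cat(sprintf("<rate_map> %d x %d bins of %g cm, %d spikes, peak %.2f Hz\n",
              nrow(x$rate), ncol(x$rate), x$bin_size, x$n_spikes_used,
              suppressWarnings(max(x$rate, na.rm = TRUE))))
  invisible(x)
}

#' Gaussian-smooth a rate map (mask-normalized)
#'
#' Convolves the rate with a normalized Gaussian kernel, excluding invalid
#' bins from both the numerator and the normalization so rates never bleed
#' across unvisited territory. Constant maps are unchanged.
#'
#' @param map a [compute_rate_map()] result.
#' @param sigma Gaussian SD in bins.
#' @return a `rate_map` with smoothed `rate` and a `peak_rate` field.
#' @export
smooth_map_gaussian <- function(map, sigma = 1.25) {
  stopifnot(inherits(map, "rate_map"))
  k <- gaussian_kernel_1d(sigma)
  r0 <- ifelse(map$valid, map$rate, 0)
  m0 <- map$valid * 1
  num <- conv2_separable(r0, k)
  den <- conv2_separable(m0, k)
  sm <- matrix(NA_real_, nrow(map$rate), ncol(map$rate))
  sm[map$valid] <- num[map$valid] / den[map$valid]
  out <- map
  out$rate <- sm
  out$peak_rate <- max(sm[map$valid])
  out
}

#' @noRd
conv2_separable <- function(m, k) {
  # zero-padded separable convolution by shift-and-add
  r <- (length(k) - 1L) / 2L
  conv_dim <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    n <- if (along == 1) nrow(m) else ncol(m)
    for (off in -r:r) {
      w <- k[off + r + 1L]
      src <- seq_len(n) + off
      okk <- src >= 1 & src <= n
      if (along == 1) out[okk, ] <- out[okk, ] + w * m[src[okk], ]
      else out[, okk] <- out[, okk] + w * m[, src[okk]]
    }
    out
  }
  conv_dim(conv_dim(m, 1), 2)
}

#' Adaptive-binned rate map
#'
#' For every visited bin, a sampling circle grows until the spike count
#' inside it exceeds `alpha / (n_occ^2 * r^2)` where `n_occ` is the number of
#' position samples inside the circle and `r` its radius in bins; the bin's
#' rate is then spikes-in-circle / dwell-in-circle. The radius is capped at
#' the map diagonal (a cell with no spikes gets rate 0 everywhere).
#'
#' @inheritParams compute_rate_map
#' @param alpha scaling constant of the adaptive algorithm.
#' @return a `rate_map` whose `rate` holds the adaptive estimates.
#' @export
adaptive_rate_map <- function(session, spikes, bin_size, alpha = 1e6,
                              speed_min = 2, occ_min = 0.4, bounds = NULL) {
  raw <- compute_rate_map(session, spikes, bin_size, speed_min, occ_min, bounds)
  adaptive_smooth(raw, session, alpha = alpha)
}

#' Adaptive smoothing of an existing raw map
#'
#' @param raw a [compute_rate_map()] result.
#' @param session the tracked session the map came from (for the sample
#'   count per bin; dwell alone would conflate sampling rate and time).
#' @param alpha scaling constant.
#' @return a `rate_map`.
#' @export
adaptive_smooth <- function(raw, session, alpha = 1e6) {
  stopifnot(inherits(raw, "rate_map"))
  nx <- nrow(raw$rate); ny <- ncol(raw$rate)
  visited <- which(raw$occupancy > 0)
  if (!length(visited)) abort("empty occupancy map")
  # samples per bin approximated from dwell at the median frame interval
  dt <- stats::median(diff(session$time_s))
  n_samp <- raw$occupancy / dt
  bx <- ((visited - 1L) %% nx) + 1L
  by <- ((visited - 1L) %/% nx) + 1L
  occ_v <- raw$occupancy[visited]
  nsmp_v <- n_samp[visited]
  cnt_v <- raw$spikes[visited]
  out_rate <- matrix(NA_real_, nx, ny)
  for (b in seq_along(visited)) {
    d <- sqrt((bx - bx[b])^2 + (by - by[b])^2)
    ord <- order(d)
    dd <- pmax(d[ord], 1)
    occ_c <- cumsum(occ_v[ord])
    smp_c <- cumsum(nsmp_v[ord])
    cnt_c <- cumsum(cnt_v[ord])
    hit <- which(cnt_c > alpha / (smp_c^2 * dd^2))
    k <- if (length(hit)) hit[1] else length(ord)
    out_rate[visited[b]] <- if (occ_c[k] > 0) cnt_c[k] / occ_c[k] else 0
  }
  out <- raw
  out$rate <- ifelse(raw$valid, out_rate, NA_real_)
  out$adaptive_alpha <- alpha
  out
}

#' Skaggs spatial information score
#'
#' Information (bits) about the animal's location conveyed by a single
#' spike: `I = sum_i p_i (r_i / R) log2(r_i / R)` over valid bins, with
#' `p_i` the occupancy share, `r_i` the bin rate and `R` the
#' occupancy-weighted mean rate. Zero-rate bins contribute zero.
#'
#' @param map a `rate_map` (raw, smoothed or adaptive).
#' @return information in bits/spike, or NA (with a warning) when the mean
#'   rate is zero.
#' @export
spatial_information <- function(map) {
  stopifnot(inherits(map, "rate_map"))
  v <- map$valid
  p <- map$occupancy[v] / sum(map$occupancy[v])
  r <- map$rate[v]
  R <- sum(p * r)
  if (!is.finite(R) || R <= 0) {
    warning("mean rate is zero; spatial information undefined")
    return(NA_real_)
  }
  nz <- r > 0
  sum(p[nz] * (r[nz] / R) * log2(r[nz] / R))
}

#' Place field
#' @noRd
place_field <- function(bins, size, peak_rate) {
  structure(list(bins = bins, size = size, peak_rate = peak_rate),
            class = "place_field")
}

#' Segment place fields in a smoothed rate map
#'
#' Starting from each local rate maximum in descending order, a candidate
#' field is the 4-connected component of bins whose rate exceeds 15% of that
#' field's own peak. Fields whose peak is at most 25% of the map peak, or
#' that span fewer than `min_bins` bins, are discarded. Each bin belongs to
#' at most one field (the one grown from the higher peak).
#'
#' @param smoothed a [smooth_map_gaussian()] result.
#' @param min_bins minimum field extent, bins.
#' @param rate_fraction member threshold as a fraction of the field peak.
#' @param map_peak_fraction minimum field peak as a fraction of the map peak.
#' @return list of `place_field` (bin indices, size in bins, peak rate),
#'   sorted by decreasing size; empty list when nothing qualifies.
#' @export
detect_place_fields <- function(smoothed, min_bins = 7,
                                rate_fraction = 0.15,
                                map_peak_fraction = 0.25) {
  stopifnot(inherits(smoothed, "rate_map"))
  r <- smoothed$rate
  nx <- nrow(r); ny <- ncol(r)
  vr <- ifelse(smoothed$valid & !is.na(r), r, -Inf)
  map_peak <- max(vr)
  if (!is.finite(map_peak) || map_peak <= 0) return(list())
  # local maxima over the 4-neighbourhood
  is_max <- matrix(TRUE, nx, ny)
  shift_cmp <- function(dx, dy) {
    cmp <- matrix(-Inf, nx, ny)
    sx <- seq_len(nx) + dx; sy <- seq_len(ny) + dy
    okx <- sx >= 1 & sx <= nx; oky <- sy >= 1 & sy <= ny
    cmp[okx, oky] <- vr[sx[okx], sy[oky]]
    cmp
  }
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    is_max <- is_max & (vr >= shift_cmp(d[1], d[2]))
  peaks <- which(is_max & is.finite(vr) & vr > 0)
  peaks <- peaks[order(-vr[peaks])]
  assigned <- matrix(FALSE, nx, ny)
  fields <- list()
  for (p in peaks) {
    if (assigned[p]) next
    peak_rate <- vr[p]
    mask <- matrix(FALSE, nx, ny)
    mask[is.finite(vr) & vr > rate_fraction * peak_rate & !assigned] <- TRUE
    lab <- label_components(mask, connectivity = 4)
    comp <- lab == lab[p]
    bins <- which(comp)
    assigned[bins] <- TRUE
    # the component may contain a higher summit only if it was already
    # assigned, so vr[p] is this field's peak
    if (length(bins) < min_bins) next
    if (peak_rate <= map_peak_fraction * map_peak) next
    fields[[length(fields) + 1L]] <- place_field(bins, length(bins), peak_rate)
  }
  fields[order(-vapply(fields, function(f) f$size, numeric(1)))]
}

#' Plot a rate map
#' @param x a `rate_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.rate_map <- function(x, ...) {
  graphics::image(x = x$x_edges, y = x$y_edges, z = x$rate,
                  xlab = "x (cm)", ylab = "y (cm)", useRaster = TRUE, ...)
  invisible(x)
}
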