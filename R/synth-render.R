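# Rendering of synthetic sessions: LED video frames, per-camera clocks and
# TTL logs, and calibration scenes for registration, all with known ground
# truth.
#
# Image convention: a colour frame is a numeric array [rows (y), cols (x), 3]
# with channel values in 0..255; a grayscale frame is a [rows, cols] matrix.
# Pixel centres sit at integer coordinates, x = column, y = row, from 1.

#' Simulate one camera's frame clock
#'
#' Capture times on the acquisition clock follow the nominal rate plus the
#' camera's IFI jitter model; frames are then dropped independently with the
#' camera's drop probability, and device timestamps are derived through the
#' camera's offset + drift clock.
#'
#' @param camera a [camera_model()].
#' @param duration session length on the acquisition clock, seconds.
#' @param seed integer seed.
#' @param start_lag_s start time of the first frame, seconds.
#' @return list with `acq_times` (true capture times, acquisition clock),
#'   `device_times` (logged timestamps, device clock) and `frame_index`
#'   (index in the undropped sequence).
#' @export
simulate_frame_clock <- function(camera, duration, seed, start_lag_s = 0) {
  stopifnot(inherits(camera, "camera_model"))
  n <- floor((duration - start_lag_s) * camera$frame_rate) + 1L
  with_local_seed(seed, {
    dev <- sample_ifi_deviations(camera$jitter, n - 1L)
    ifis <- 1 / camera$frame_rate + dev
    acq <- start_lag_s + c(0, cumsum(ifis))
    keep <- rep(TRUE, n)
    if (camera$drop_prob > 0 && n > 1) {
      keep[-1] <- stats::runif(n - 1L) >= camera$drop_prob
    }
    acq <- acq[keep]
    list(acq_times = acq,
         device_times = camera$clock_offset + (1 + camera$clock_drift) * acq,
         frame_index = which(keep))
  })
}

#' @noRd
sample_ifi_deviations <- function(jitter, n) {
  if (n <= 0) return(numeric(0))
  if (is.null(jitter)) return(rep(0, n))
  if (is.function(jitter)) return(jitter(n))
  sample(as.numeric(jitter), n, replace = TRUE)
}

#' Sample interframe intervals from an empirical pool
#'
#' Draws `n` IFIs i.i.d. with replacement from `pool`, seeded.
#'
#' @param pool nonempty numeric vector of observed IFIs, seconds.
#' @param n number of intervals to draw (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_empirical_ifis <- function(pool, n, seed) {
  if (length(pool) == 0) abort("IFI pool must be nonempty")
  if (!is_scalar_num(n) || n < 1) abort("n must be >= 1")
  with_local_seed(seed, sample(as.numeric(pool), n, replace = TRUE))
}

#' Synthetic IFI pools for a high-jitter and a low-jitter camera
#'
#' `commercial_ifi_pool()` emulates a frame-grabber camera with roughly
#' normally distributed IFI deviations spanning +/-7 ms, calibrated so about
#' 40% of frames deviate by more than 1 ms. `picamera_ifi_pool()` emulates a
#' hardware-timestamped camera with deviations within +/-0.025 ms, most
#' within +/-0.002 ms. Both are approximations to published summary
#' statistics, not measured distributions.
#'
#' @param n pool size.
#' @param rate nominal frame rate, Hz.
#' @param seed integer seed.
#' @return numeric vector of IFIs, seconds.
#' @export
commercial_ifi_pool <- function(n = 20000, rate = 25, seed = 1) {
  # sd so that P(|dev| > 1 ms) = 0.4; resample the (negligible) tail beyond
  # the published +/-7 ms range
  sd_ms <- 1 / stats::qnorm(0.8)
  with_local_seed(seed, {
    dev <- stats::rnorm(n, 0, sd_ms)
    while (any(abs(dev) > 7)) {
      bad <- abs(dev) > 7
      dev[bad] <- stats::rnorm(sum(bad), 0, sd_ms)
    }
    1 / rate + dev / 1000
  })
}

#' @rdname commercial_ifi_pool
#' @export
picamera_ifi_pool <- function(n = 20000, rate = 30, seed = 1) {
  sd_ms <- 0.001 / stats::qnorm(0.8) # most frames within +/-0.002 ms
  with_local_seed(seed, {
    dev <- stats::rnorm(n, 0, sd_ms)
    while (any(abs(dev) > 0.025)) {
      bad <- abs(dev) > 0.025
      dev[bad] <- stats::rnorm(sum(bad), 0, sd_ms)
    }
    1 / rate + dev / 1000
  })
}

#' Render a synthetic recording session
#'
#' Projects the two head LEDs (red anterior, green posterior) through each
#' camera's homography and renders them as saturated discs on a dark
#' background, frame by frame, on each camera's own (jittered, drifting)
#' clock. An LED is absent from a camera's frame when an occluder blocks that
#' camera's view at the LED's arena position or when it falls outside the
#' camera's image.
#'
#' Frames are generated lazily: each camera's `frame(i)` closure renders
#' frame `i` on demand, so long sessions do not need the full video in
#' memory.
#'
#' @param traj a [simulate_trajectory()] result.
#' @param cameras list of [camera_model()] (>= 1).
#' @param arena the [arena_spec()] (holds the occluders).
#' @param led_geometry list with `red_forward_cm` and `green_back_cm`:
#'   distances of the anterior red and posterior green LED from the head
#'   centre along the heading, cm.
#' @param seed integer seed (drives clocks and any pixel noise).
#' @param start_lag_s per-camera start lags, seconds (recycled).
#' @param led_radius_px rendered LED disc radius, pixels.
#' @param noise_sd additive Gaussian pixel noise SD (0..255 scale); 0 = none.
#' @return object of class `rendered_session`: list with one element per
#'   camera, each containing `camera`, `timestamps` (device-clock
#'   [frame_timestamp_series()]), `acq_times`, `truth` (per-frame LED and head
#'   ground truth in cm, plus per-LED visibility for this camera) and
#'   `frame(i)`.
#' @export
render_session <- function(traj, cameras, arena,
                           led_geometry = list(red_forward_cm = 2, green_back_cm = 2),
                           seed = 1, start_lag_s = 0,
                           led_radius_px = 3, noise_sd = 0) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(cameras) == 0) abort("need at least one camera")
  start_lag_s <- rep_len(start_lag_s, length(cameras))
  duration <- max(traj$times)
  out <- vector("list", length(cameras))
  for (ci in seq_along(cameras)) {
    cam <- cameras[[ci]]
    clk <- simulate_frame_clock(cam, duration, seed = seed + 1000L * ci,
                                start_lag_s = start_lag_s[ci])
    samp <- sample_trajectory(traj, clk$acq_times)
    u <- cbind(cos(samp$hd_deg * pi / 180), sin(samp$hd_deg * pi / 180))
    red <- cbind(samp$x_cm, samp$y_cm) + led_geometry$red_forward_cm * u
    green <- cbind(samp$x_cm, samp$y_cm) - led_geometry$green_back_cm * u
    red_px <- apply_homography(cam$H, red)
    green_px <- apply_homography(cam$H, green)
    vis <- function(canvas, px) {
      inside <- px[, 1] >= 1 & px[, 1] <= cam$image_size[1] &
        px[, 2] >= 1 & px[, 2] <= cam$image_size[2]
      inside & !point_occluded(arena, cam$id, canvas[, 1], canvas[, 2])
    }
    truth <- data.frame(
      acq_time_s = clk$acq_times,
      x_cm = samp$x_cm, y_cm = samp$y_cm, hd_deg = samp$hd_deg,
      red_x_cm = red[, 1], red_y_cm = red[, 2],
      green_x_cm = green[, 1], green_y_cm = green[, 2],
      red_px_x = red_px[, 1], red_px_y = red_px[, 2],
      green_px_x = green_px[, 1], green_px_y = green_px[, 2],
      red_visible = vis(red, red_px),
      green_visible = vis(green, green_px)
    )
    frame_fun <- local({
      cam_l <- cam; truth_l <- truth
      r_px <- led_radius_px; nsd <- noise_sd; base_seed <- seed + 1000L * ci
      function(i) {
        stopifnot(i >= 1, i <= nrow(truth_l))
        render_led_frame(
          cam_l$image_size,
          red_px = if (truth_l$red_visible[i]) c(truth_l$red_px_x[i], truth_l$red_px_y[i]),
          green_px = if (truth_l$green_visible[i]) c(truth_l$green_px_x[i], truth_l$green_px_y[i]),
          radius = r_px, noise_sd = nsd, seed = base_seed + i)
      }
    })
    out[[ci]] <- list(camera = cam,
                      timestamps = frame_timestamp_series(clk$device_times,
                                                          cam$frame_rate, cam$id),
                      acq_times = clk$acq_times,
                      truth = truth,
                      frame = frame_fun)
  }
  structure(out, class = "rendered_session")
}

#' Render a single LED frame
#'
#' @param image_size c(width, height) pixels.
#' @param red_px,green_px LED centres in pixel coordinates, or NULL if absent.
#' @param radius disc radius, pixels.
#' @param noise_sd additive Gaussian noise SD on the 0..255 scale (clipped).
#' @param seed seed for the noise (ignored when `noise_sd` is 0).
#' @return numeric array [height, width, 3], values 0..255.
#' @export
render_led_frame <- function(image_size, red_px = NULL, green_px = NULL,
                             radius = 3, noise_sd = 0, seed = 1) {
  w <- image_size[1]; h <- image_size[2]
  img <- array(0, dim = c(h, w, 3))
  if (noise_sd > 0) {
    img <- with_local_seed(seed,
      array(pmin(pmax(stats::rnorm(h * w * 3, 10, noise_sd), 0), 255),
            dim = c(h, w, 3)))
  }
  stamp <- function(img, ctr, channel) {
    xs <- seq(max(1, floor(ctr[1] - radius)), min(w, ceiling(ctr[1] + radius)))
    ys <- seq(max(1, floor(ctr[2] - radius)), min(h, ceiling(ctr[2] + radius)))
    if (!length(xs) || !length(ys)) return(img)
    dx <- outer(ys - ctr[2], xs - ctr[1], function(a, b) sqrt(a^2 + b^2))
    sel <- which(dx <= radius, arr.ind = TRUE)
    if (nrow(sel)) {
      rows <- ys[sel[, 1]]; cols <- xs[sel[, 2]]
      for (ch in 1:3) {
        val <- if (ch == channel) 255 else 0
        img[cbind(rows, cols, ch)] <- val
      }
    }
    img
  }
  if (!is.null(red_px)) img <- stamp(img, red_px, 1L)
  if (!is.null(green_px)) img <- stamp(img, green_px, 2L)
  img
}

#' Generate a calibration scene with uniquely textured features
#'
#' Builds a planar canvas image carpeted with locally unique high-contrast
#' features (a saturated core for detection surrounded by a random
#' mid-intensity ring texture for description) and renders each camera's
#' calibration frame by inverse-warping the canvas through the camera's
#' ground-truth homography.
#'
#' @param cameras list of [camera_model()].
#' @param n_features number of features to place.
#' @param seed integer seed.
#' @param cm_per_px canvas raster resolution, cm per canvas pixel.
#' @param margin_cm canvas margin beyond the union of camera footprints.
#' @return list with `frames` (per-camera grayscale matrices, 0..255),
#'   `features` (data.frame: feature id, canvas x/y cm), `projections`
#'   (data.frame: feature, camera index, pixel x/y, visible flag), `canvas`
#'   (the canvas raster) and `canvas_origin_cm`/`cm_per_px`. Cameras that
#'   share no visible features with any other camera trigger a warning.
#' @export
generate_calibration_scene <- function(cameras, n_features = 200, seed = 1,
                                       cm_per_px = 1, margin_cm = 10) {
  if (length(cameras) == 0) abort("need at least one camera")
  corners_cm <- do.call(rbind, lapply(cameras, function(cam) {
    w <- cam$image_size[1]; h <- cam$image_size[2]
    apply_homography(cam$H_inv, rbind(c(1, 1), c(w, 1), c(1, h), c(w, h)))
  }))
  x0 <- min(corners_cm[, 1]) - margin_cm; x1 <- max(corners_cm[, 1]) + margin_cm
  y0 <- min(corners_cm[, 2]) - margin_cm; y1 <- max(corners_cm[, 2]) + margin_cm
  nc <- ceiling((x1 - x0) / cm_per_px); nr <- ceiling((y1 - y0) / cm_per_px)
  pattern_r <- 6L # feature pattern radius in canvas pixels
  with_local_seed(seed, {
    # jittered grid keeps features separated by at least one pattern width
    aspect <- (x1 - x0) / (y1 - y0)
    gx <- ceiling(sqrt(n_features * aspect))
    gy <- ceiling(n_features / gx)
    cw <- (x1 - x0) / gx; ch <- (y1 - y0) / gy
    centers <- expand.grid(ix = seq_len(gx), iy = seq_len(gy))[seq_len(min(n_features, gx * gy)), ]
    fx <- x0 + (centers$ix - 0.5) * cw + stats::runif(nrow(centers), -0.25, 0.25) * cw
    fy <- y0 + (centers$iy - 0.5) * ch + stats::runif(nrow(centers), -0.25, 0.25) * ch
    canvas <- matrix(0, nr, nc)
    for (f in seq_along(fx)) {
      cxp <- round((fx[f] - x0) / cm_per_px) + 1L
      cyp <- round((fy[f] - y0) / cm_per_px) + 1L
      # snap the feature centre to its canvas pixel so detection truth is exact
      fx[f] <- x0 + (cxp - 1L) * cm_per_px
      fy[f] <- y0 + (cyp - 1L) * cm_per_px
      xs <- (cxp - pattern_r):(cxp + pattern_r)
      ys <- (cyp - pattern_r):(cyp + pattern_r)
      ok <- xs >= 1 & xs <= nc
      oky <- ys >= 1 & ys <= nr
      patch <- matrix(stats::runif((2 * pattern_r + 1)^2, 40, 170),
                      2 * pattern_r + 1, 2 * pattern_r + 1)
      dd <- outer(-pattern_r:pattern_r, -pattern_r:pattern_r,
                  function(a, b) sqrt(a^2 + b^2))
      patch[dd <= 2] <- 255    # saturated core for detection
      patch[dd > pattern_r] <- 0
      canvas[ys[oky], xs[ok]] <- pmax(canvas[ys[oky], xs[ok]],
                                      patch[oky, ok, drop = FALSE])
    }
    features <- data.frame(feature = seq_along(fx), x_cm = fx, y_cm = fy)
    frames <- vector("list", length(cameras))
    proj_rows <- list()
    for (ci in seq_along(cameras)) {
      cam <- cameras[[ci]]
      w <- cam$image_size[1]; h <- cam$image_size[2]
      grid <- cbind(rep(seq_len(w), each = h), rep(seq_len(h), w))
      cmxy <- apply_homography(cam$H_inv, grid)
      px <- (cmxy[, 1] - x0) / cm_per_px + 1
      py <- (cmxy[, 2] - y0) / cm_per_px + 1
      vals <- bilinear_sample(canvas, px, py, fill = 0)
      frames[[ci]] <- matrix(vals, nrow = h, ncol = w, byrow = FALSE)
      fpx <- apply_homography(cam$H, cbind(fx, fy))
      visible <- fpx[, 1] >= pattern_r + 1 & fpx[, 1] <= w - pattern_r &
        fpx[, 2] >= pattern_r + 1 & fpx[, 2] <= h - pattern_r
      proj_rows[[ci]] <- data.frame(feature = features$feature, camera = ci,
                                    px_x = fpx[, 1], px_y = fpx[, 2],
                                    visible = visible)
    }
    projections <- do.call(rbind, proj_rows)
    if (length(cameras) > 1) {
      vis <- table(factor(projections$feature[projections$visible],
                          levels = features$feature),
                   factor(projections$camera[projections$visible],
                          levels = seq_along(cameras)))
      for (ci in seq_along(cameras)) {
        shared <- FALSE
        for (cj in seq_along(cameras)) {
          if (ci == cj) next
          both <- sum(vis[, ci] > 0 & vis[, cj] > 0)
          if (both >= 4) shared <- TRUE
        }
        if (!shared)
          warning(sprintf("camera %d shares no features with any other camera; registration will be disconnected", ci))
      }
    }
    list(frames = frames, features = features, projections = projections,
         canvas = canvas, canvas_origin_cm = c(x0, y0), cm_per_px = cm_per_px)
  })
}
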