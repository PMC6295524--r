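# Pipeline orchestration: rig construction, configuration, and the
# end-to-end benchmark that chains registration QC, timing diagnostics,
# occlusion-robust tracking and the jitter-degradation experiment.

#' Build a grid rig of overlapping overhead cameras
#'
#' Lays `nx` x `ny` cameras over the arena so adjacent fields of view
#' overlap by `overlap_frac` of their extent, with optional per-camera
#' rotation and slight perspective to emulate imperfect mounting.
#'
#' @param arena an [arena_spec()].
#' @param nx,ny cameras along x and y.
#' @param overlap_frac fractional overlap between adjacent fields of view.
#' @param image_size per-camera sensor size, pixels.
#' @param rotations per-camera in-plane rotations, degrees (recycled).
#' @param perspective per-camera projective tilt magnitude (recycled).
#' @param frame_rate,jitter,drop_prob,clock_offsets,clock_drifts clock model
#'   parameters (offsets/drifts recycled across cameras).
#' @return list of [camera_model()].
#' @export
make_camera_rig <- function(arena, nx = 4, ny = 2, overlap_frac = 0.25,
                            image_size = c(320L, 240L), rotations = 0,
                            perspective = 0, frame_rate = 30,
                            jitter = NULL, drop_prob = 0,
                            clock_offsets = 0, clock_drifts = 0) {
  n <- nx * ny
  rotations <- rep_len(rotations, n)
  perspective <- rep_len(perspective, n)
  clock_offsets <- rep_len(clock_offsets, n)
  clock_drifts <- rep_len(clock_drifts, n)
  # FOV sized so adjacent views overlap by overlap_frac, covering the arena
  # with a small margin beyond the walls
  margin <- 0.05
  w_tot <- arena$width * (1 + 2 * margin)
  h_tot <- arena$height * (1 + 2 * margin)
  fov_w <- w_tot / (nx - (nx - 1) * overlap_frac)
  fov_h <- h_tot / (ny - (ny - 1) * overlap_frac)
  step_x <- fov_w * (1 - overlap_frac)
  step_y <- fov_h * (1 - overlap_frac)
  cams <- vector("list", n)
  idx <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      idx <- idx + 1L
      x0 <- -margin * arena$width + (ix - 1) * step_x
      y0 <- -margin * arena$height + (iy - 1) * step_y
      cams[[idx]] <- overhead_camera(
        x0, y0, fov_w, fov_h, image_size = image_size,
        rotation_deg = rotations[idx],
        perspective = c(perspective[idx], -perspective[idx]),
        frame_rate = frame_rate, clock_offset = clock_offsets[idx],
        clock_drift = clock_drifts[idx], jitter = jitter,
        drop_prob = drop_prob, id = idx)
    }
  }
  cams
}

#' Default benchmark configuration
#'
#' Flat key-value configuration for [run_benchmark()]; write and re-read it
#' with [write_config()] / [read_config()] so every tunable parameter is one
#' auditable surface.
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    arena_width_cm = 550, arena_height_cm = 300,
    rig_nx = 4, rig_ny = 2, rig_overlap = 0.25,
    image_width_px = 320, image_height_px = 240,
    frame_rate_hz = 30,
    calib_features = 260,
    ransac_px = 2,
    landmark_distance_cm = 100,
    track_duration_s = 60,
    track_frame_rate_hz = 10,
    mean_speed_cms = 15,
    intensity_threshold = 50,
    max_gap_frames = 5,
    bin_size_cm = 4,
    speed_min_cms = 2,
    occ_min_s = 0.4,
    degradation_cells = 20,
    degradation_duration_s = 1200,
    degradation_bin_cm = 2,
    shuffles = 1000,
    seed = 1
  )
}

#' @rdname default_config
#' @param config a configuration list.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  base[names(cfg)] <- cfg
  base
}

#' Run the full synthetic benchmark
#'
#' Chains the pipeline end to end on synthetic data and writes CSV/JSON
#' reports under `out_dir`:
#' registration of the multi-camera rig from a calibration scene with the
#' resulting projection-error QC; IFI jitter reports for a low-jitter and a
#' high-jitter clock model; an occlusion tracking run with its coverage and
#' RMSE against ground truth; and the jitter-degradation experiment with its
#' paired Wilcoxon statistics. Fully deterministic given the config seed.
#'
#' @param config a [default_config()]-style list.
#' @param out_dir output directory.
#' @return invisibly, the summary list (also written to `summary.json`).
#' @export
run_benchmark <- function(config = default_config(), out_dir = tempfile("benchmark")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  arena <- arena_spec(config$arena_width_cm, config$arena_height_cm)
  rig <- make_camera_rig(arena, nx = config$rig_nx, ny = config$rig_ny,
                         overlap_frac = config$rig_overlap,
                         image_size = c(config$image_width_px, config$image_height_px),
                         rotations = seq(-2, 2, length.out = config$rig_nx * config$rig_ny),
                         frame_rate = config$frame_rate_hz)

  # --- registration QC -------------------------------------------------
  scene <- generate_calibration_scene(rig, n_features = config$calib_features,
                                      seed = seed)
  regs <- build_canvas(scene$frames, ref_camera = 1,
                       ransac_px = config$ransac_px, seed = seed,
                       landmark = scene_landmark(scene, config$landmark_distance_cm))
  grid_pts <- noisy_grid_observations(rig, arena, noise_px = 0.5, seed = seed)
  proj <- projection_error(grid_pts, regs)
  utils::write.csv(proj$errors, file.path(out_dir, "projection_errors.csv"),
                   row.names = FALSE)

  # --- timing QC -------------------------------------------------------
  lo_cam <- overhead_camera(0, 0, 100, 75, frame_rate = config$frame_rate_hz,
                            jitter = picamera_ifi_pool(rate = config$frame_rate_hz) -
                              1 / config$frame_rate_hz)
  hi_cam <- overhead_camera(0, 0, 100, 75, frame_rate = config$frame_rate_hz,
                            jitter = commercial_ifi_pool(rate = config$frame_rate_hz) -
                              1 / config$frame_rate_hz)
  lo_clk <- simulate_frame_clock(lo_cam, 120, seed = seed)
  hi_clk <- simulate_frame_clock(hi_cam, 120, seed = seed + 1)
  lo_rep <- ifi_report(frame_timestamp_series(lo_clk$acq_times, config$frame_rate_hz, "low_jitter"))
  hi_rep <- ifi_report(frame_timestamp_series(hi_clk$acq_times, config$frame_rate_hz, "high_jitter"))
  write_jitter_report(lo_rep, csv_path = file.path(out_dir, "ifi_low_jitter.csv"),
                      json_path = file.path(out_dir, "ifi_low_jitter.json"))
  write_jitter_report(hi_rep, csv_path = file.path(out_dir, "ifi_high_jitter.csv"),
                      json_path = file.path(out_dir, "ifi_high_jitter.json"))

  # --- occlusion tracking ---------------------------------------------
  occl <- occlusion_benchmark(config, seed)
  write_tracking(occl$tracked, file.path(out_dir, "tracking_occlusion.csv"))

  # --- jitter degradation ---------------------------------------------
  deg <- degradation_benchmark(config, seed)
  utils::write.csv(deg$metrics, file.path(out_dir, "jitter_degradation.csv"),
                   row.names = FALSE)

  summary <- list(
    schema = "arenatrack.benchmark.v1",
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("arenatrack")),
    seed = seed,
    config_hash = config_hash(config),
    registration = list(
      n_cameras = length(rig),
      projection_error_median_cm = proj$overall_median_cm,
      projection_error_max_cm = proj$overall_max_cm),
    timing = list(
      low_jitter_range_ms = as.list(lo_rep$jitter_range_s * 1000),
      high_jitter_range_ms = as.list(hi_rep$jitter_range_s * 1000)),
    occlusion = list(coverage = occl$coverage, rmse_cm = occl$rmse_cm),
    degradation = lapply(deg$tests, function(t) list(z = t$z, p = t$p_value))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

#' Landmark for metric scale from a calibration scene
#' @noRd
scene_landmark <- function(scene, distance_cm) {
  # two ground-truth features visible in camera 1, distance known exactly
  p1 <- scene$projections[scene$projections$camera == 1 & scene$projections$visible, ]
  if (nrow(p1) < 2) abort("camera 1 sees fewer than 2 features; cannot set scale")
  f <- scene$features
  a <- p1[1, ]
  d <- sqrt((f$x_cm[a$feature] - f$x_cm[p1$feature])^2 +
              (f$y_cm[a$feature] - f$y_cm[p1$feature])^2)
  b <- p1[which.max(d), ]
  list(camera = 1, p1 = c(a$px_x, a$px_y), p2 = c(b$px_x, b$px_y),
       distance_cm = max(d))
}

#' Simulated string-grid intersections observed with pixel noise
#' @noRd
noisy_grid_observations <- function(rig, arena, spacing_cm = 50,
                                    noise_px = 0.5, seed = 1) {
  gx <- seq(spacing_cm, arena$width - 1, by = spacing_cm)
  gy <- seq(spacing_cm, arena$height - 1, by = spacing_cm)
  pts <- expand.grid(x = gx, y = gy)
  with_local_seed(seed, {
    rows <- list()
    for (ci in seq_along(rig)) {
      cam <- rig[[ci]]
      px <- apply_homography(cam$H, as.matrix(pts))
      vis <- px[, 1] >= 1 & px[, 1] <= cam$image_size[1] &
        px[, 2] >= 1 & px[, 2] <= cam$image_size[2]
      if (!any(vis)) next
      rows[[length(rows) + 1L]] <- data.frame(
        intersection = which(vis), camera = ci,
        px_x = px[vis, 1] + stats::rnorm(sum(vis), 0, noise_px),
        px_y = px[vis, 2] + stats::rnorm(sum(vis), 0, noise_px))
    }
    do.call(rbind, rows)
  })
}

#' Occlusion tracking benchmark: LED visible to one of four cameras
#' @noRd
occlusion_benchmark <- function(config = default_config(), seed = 1) {
  arena <- arena_spec(100, 100,
                      occluders = list(list(xmin = 30, xmax = 70,
                                            ymin = 30, ymax = 70,
                                            cameras = c(2L, 3L, 4L))))
  rig <- make_camera_rig(arena, nx = 2, ny = 2, overlap_frac = 0.6,
                         image_size = c(320L, 240L),
                         frame_rate = config$track_frame_rate_hz)
  regs <- lapply(seq_along(rig), function(ci)
    camera_registration(ci, rig[[ci]]$H_inv, inliers = NA_integer_,
                        cm_per_px = NA_real_))
  traj <- simulate_trajectory(arena, config$track_duration_s,
                              config$mean_speed_cms, seed = seed + 7)
  sess <- render_session(traj, rig, arena, seed = seed + 8)
  tracked <- track_session(sess, regs,
                           intensity_threshold = config$intensity_threshold,
                           max_gap = config$max_gap_frames)
  gt <- sample_trajectory(traj, tracked$time_s)
  err <- sqrt((tracked$x_cm - gt$x_cm)^2 + (tracked$y_cm - gt$y_cm)^2)
  list(tracked = tracked,
       coverage = mean(!is.na(tracked$x_cm)),
       rmse_cm = sqrt(mean(err^2, na.rm = TRUE)),
       arena = arena, rig = rig, traj = traj)
}

#' Jitter degradation benchmark on synthetic place cells
#' @noRd
degradation_benchmark <- function(config = default_config(), seed = 1,
                                  ifi_pool = NULL) {
  arena <- arena_spec(100, 100)
  traj <- simulate_trajectory(arena, config$degradation_duration_s,
                              config$mean_speed_cms, seed = seed + 17)
  frame_times <- seq(0, config$degradation_duration_s,
                     by = 1 / config$frame_rate_hz)
  session <- session_from_trajectory(traj, frame_times)
  n_cells <- config$degradation_cells
  cells <- lapply(seq_len(n_cells), function(i) {
    ctr <- with_local_seed(seed + 100L + i, stats::runif(2, 20, 80))
    simulate_spikes(traj, neuron_spec("place", center = ctr, sigma = 8,
                                      peak_rate = 12, baseline_rate = 0.1),
                    seed = seed + 200L + i)
  })
  pool <- ifi_pool %||% commercial_ifi_pool(rate = config$frame_rate_hz,
                                            seed = seed + 3)
  jitter_degradation_experiment(session, cells, pool, seed = seed + 4,
                                bin_size = config$degradation_bin_cm)
}

#' @noRd
config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(v) paste(format(v), collapse = ","),
                                   character(1)), sep = "=", collapse = ";")
  # small stable polynomial hash; avoids external digest dependencies
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
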