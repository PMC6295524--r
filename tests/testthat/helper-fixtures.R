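# Shared fixtures, built lazily and cached for the whole test run.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, value) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, value, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# 1200 s study session at 30 Hz used by the neuro tests: long enough for
# dense occupancy at 2-cm bins and the 0.4 s occupancy filter.
fx_study_traj <- function() fixture("study_traj",
  simulate_trajectory(arena_spec(100, 100), 1200, 15, seed = 11))

fx_study_session <- function() fixture("study_session",
  session_from_trajectory(fx_study_traj(), seq(0, 1200, by = 1 / 30)))

fx_place_spikes <- function() fixture("place_spikes",
  simulate_spikes(fx_study_traj(),
                  neuron_spec("place", center = c(40, 60), sigma = 8,
                              peak_rate = 12, baseline_rate = 0.1),
                  seed = 5))

# Two overlapping cameras plus their calibration scene for registration tests.
fx_two_cams <- function() fixture("two_cams", list(
  overhead_camera(0, 0, 120, 90, image_size = c(240L, 180L),
                  rotation_deg = 1.5, id = 1L),
  overhead_camera(60, 0, 120, 90, image_size = c(240L, 180L),
                  rotation_deg = -2, perspective = c(2e-5, -1e-5), id = 2L)))

fx_two_cam_scene <- function() fixture("two_cam_scene",
  generate_calibration_scene(fx_two_cams(), n_features = 100, seed = 3))

# A straight eastward pass, as a hand-built trajectory (constant heading),
# used for phase-precession ground-truth checks.
fx_straight_run <- function(speed = 20, duration = 5, y = 50, dt = 0.002) {
  n <- floor(duration / dt) + 1L
  times <- (seq_len(n) - 1L) * dt
  structure(list(times = times, x = speed * times, y = rep(y, n),
                 hd_deg = rep(0, n), dt = dt),
            class = "trajectory")
}

# Minimal hand-built rate_map for formula-level tests.
manual_rate_map <- function(rate, occupancy, bin_size = 2,
                            valid = !is.na(rate)) {
  rate <- as.matrix(rate); occupancy <- as.matrix(occupancy)
  spikes <- ifelse(valid, rate * occupancy, 0)
  structure(list(bin_size = bin_size,
                 x_edges = seq(0, nrow(rate) * bin_size, by = bin_size),
                 y_edges = seq(0, ncol(rate) * bin_size, by = bin_size),
                 occupancy = occupancy, spikes = spikes,
                 rate = ifelse(valid, rate, NA_real_), valid = valid,
                 n_spikes_used = sum(spikes[valid]),
                 mean_rate = sum(spikes[valid]) / sum(occupancy[valid])),
            class = "rate_map")
}

# Stationary tracked session dwelling in chosen spots; for single-bin and
# speed-filter rate-map arithmetic. speed_cms is set explicitly.
manual_session <- function(times, x, y, speed, hd = 0) {
  n <- length(times)
  pos <- cbind(rep_len(x, n), rep_len(y, n))
  tracked_session(times, pos, pos, pos, rep_len(hd, n),
                  rep_len(speed, n), rep(1L, n))
}

# Ground-truth pairwise correspondences between two cameras from shared
# canvas grid points (optionally with pixel noise).
gt_pair_matches <- function(cam_a, cam_b, spacing = 10, noise_px = 0,
                            seed = 1) {
  corners <- apply_homography(cam_a$H_inv,
    rbind(c(1, 1), c(cam_a$image_size[1], cam_a$image_size[2])))
  lo <- pmin(corners[1, ], corners[2, ]) - 50
  hi <- pmax(corners[1, ], corners[2, ]) + 50
  pts <- as.matrix(expand.grid(x = seq(lo[1], hi[1], by = spacing),
                               y = seq(lo[2], hi[2], by = spacing)))
  pa <- apply_homography(cam_a$H, pts)
  pb <- apply_homography(cam_b$H, pts)
  ok <- pa[, 1] >= 1 & pa[, 1] <= cam_a$image_size[1] &
    pa[, 2] >= 1 & pa[, 2] <= cam_a$image_size[2] &
    pb[, 1] >= 1 & pb[, 1] <= cam_b$image_size[1] &
    pb[, 2] >= 1 & pb[, 2] <= cam_b$image_size[2]
  pa <- pa[ok, , drop = FALSE]; pb <- pb[ok, , drop = FALSE]
  if (noise_px > 0) {
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(2 * (nrow(pa) + nrow(pb)), 0, noise_px), ncol = 4))
    pa <- pa + noise[, 1:2]; pb <- pb + noise[, 3:4]
  }
  correspondence_set(pa, pb)
}

rel_h_error <- function(H_est, H_true) {
  H_est <- H_est / H_est[3, 3]; H_true <- H_true / H_true[3, 3]
  norm(H_est - H_true, "F") / norm(H_true, "F")
}
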