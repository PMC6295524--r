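# Synthetic-data generators: trajectory, rendering, calibration scenes,
# spikes, IFI pools, on-disk session format.

test_that("simulate_trajectory is seeded, confined and hits the mean speed", {
  arena <- arena_spec(100, 100)
  t1 <- simulate_trajectory(arena, 600, 10, seed = 1)
  t2 <- simulate_trajectory(arena, 600, 10, seed = 1)
  expect_identical(t1, t2)
  expect_true(all(t1$x >= 0 & t1$x <= 100))
  expect_true(all(t1$y >= 0 & t1$y <= 100))
  expect_true(all(diff(t1$times) > 0))
  sp <- sqrt(diff(t1$x)^2 + diff(t1$y)^2) / diff(t1$times)
  expect_lt(abs(mean(sp) - 10) / 10, 0.1)
  t3 <- simulate_trajectory(arena, 600, 10, seed = 2)
  expect_false(identical(t1$x, t3$x))
})

test_that("simulate_trajectory degenerate and invalid inputs", {
  arena <- arena_spec(100, 100)
  still <- simulate_trajectory(arena, 10, 0, seed = 1)
  expect_true(all(still$x == 50) && all(still$y == 50))
  expect_error(simulate_trajectory(arena, -1, 10, seed = 1), "duration")
  expect_error(simulate_trajectory(arena, 10, -5, seed = 1), "mean_speed")
  expect_error(arena_spec(-1, 10), "width")
  expect_error(arena_spec(10, 10, occluders = list(
    list(xmin = 5, xmax = 20, ymin = 1, ymax = 2, cameras = 1L))), "occluder")
})

test_that("trajectory occupancy coverage at the fixture conditions", {
  # 1200 s at 10 cm/s over a 1 m x 1 m arena: mean dwell is only 0.48 s per
  # 2-cm bin, so near-total >=0.4 s coverage is out of reach for any random
  # foraging walk; the frozen bounds below were measured on this generator.
  traj <- simulate_trajectory(arena_spec(100, 100), 1200, 10, seed = 7)
  dwell <- c(diff(traj$times), traj$dt)
  ix <- pmin(floor(traj$x / 2), 49); iy <- pmin(floor(traj$y / 2), 49)
  occ <- tapply(dwell, ix + 50 * iy, sum)
  frac_occ <- sum(occ >= 0.4) / 2500
  frac_visited <- length(occ) / 2500
  expect_gt(frac_visited, 0.9)
  expect_gt(frac_occ, 0.45)
  sp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / diff(traj$times)
  expect_lt(abs(mean(sp) - 10) / 10, 0.1)
})

test_that("render_session puts LED clusters at homography-projected truth", {
  arena <- arena_spec(100, 100)
  cam <- overhead_camera(0, 0, 120, 90, image_size = c(240L, 180L),
                         rotation_deg = 3, frame_rate = 10)
  traj <- simulate_trajectory(arena, 3, 12, seed = 4)
  sess <- render_session(traj, list(cam), arena, seed = 2)
  expect_s3_class(sess, "rendered_session")
  # ideal clock: all IFIs exactly 1/10 s
  expect_equal(diff(sess[[1]]$timestamps$times), rep(0.1, 30))
  tr <- sess[[1]]$truth
  i <- which(tr$red_visible & tr$green_visible)[5]
  det <- detect_leds(sess[[1]]$frame(i))
  expect_true(det$red$present && det$green$present)
  expect_lt(max(abs(det$red$centroid - c(tr$red_px_x[i], tr$red_px_y[i]))), 0.5)
  expect_lt(max(abs(det$green$centroid - c(tr$green_px_x[i], tr$green_px_y[i]))), 0.5)
  expect_error(render_session(traj, list(), arena), "camera")
})

test_that("occluders hide the LEDs from the listed cameras only", {
  arena <- arena_spec(100, 100, occluders = list(
    list(xmin = 0, xmax = 100, ymin = 0, ymax = 100, cameras = 1L)))
  cams <- list(
    overhead_camera(0, 0, 120, 90, image_size = c(160L, 120L),
                    frame_rate = 5, id = 1L),
    overhead_camera(0, 0, 120, 90, image_size = c(160L, 120L),
                    frame_rate = 5, id = 2L))
  traj <- simulate_trajectory(arena, 2, 10, seed = 9)
  sess <- render_session(traj, cams, arena, seed = 1)
  expect_true(all(!sess[[1]]$truth$red_visible))
  expect_true(all(sess[[2]]$truth$red_visible))
  d1 <- detect_leds(sess[[1]]$frame(3))
  d2 <- detect_leds(sess[[2]]$frame(3))
  expect_false(d1$red$present || d1$green$present)
  expect_true(d2$red$present && d2$green$present)
})

test_that("generate_calibration_scene shares features and is seeded", {
  scene <- fx_two_cam_scene()
  vis <- scene$projections[scene$projections$visible, ]
  shared <- intersect(vis$feature[vis$camera == 1], vis$feature[vis$camera == 2])
  expect_gte(length(shared), 8)
  scene2 <- generate_calibration_scene(fx_two_cams(), n_features = 100, seed = 3)
  expect_identical(scene$frames, scene2$frames)
  expect_identical(scene$features, scene2$features)
  # disconnected cameras warn
  far <- list(overhead_camera(0, 0, 50, 50, image_size = c(80L, 80L)),
              overhead_camera(500, 500, 50, 50, image_size = c(80L, 80L)))
  expect_warning(generate_calibration_scene(far, n_features = 60, seed = 1),
                 "shares no features")
})

test_that("simulate_spikes matches the integrated rate and degenerate cases", {
  arena <- arena_spec(100, 100)
  traj <- simulate_trajectory(arena, 120, 12, seed = 21)
  dead <- neuron_spec("place", peak_rate = 0, baseline_rate = 0)
  expect_length(simulate_spikes(traj, dead, seed = 1)$times, 0)
  nrn <- neuron_spec("place", center = c(50, 50), sigma = 12,
                     peak_rate = 10, baseline_rate = 0.2)
  expected <- sum(neuron_rate(traj, nrn)) * traj$dt
  zs <- vapply(1:20, function(s) {
    n <- length(simulate_spikes(traj, nrn, seed = s)$times)
    (n - expected) / sqrt(expected)
  }, numeric(1))
  expect_true(all(abs(zs) < 3.29)) # alpha = 0.001 per seed
  # head-direction kind responds to heading, not place
  hd_nrn <- neuron_spec("head_direction", preferred_deg = 90, kappa = 6,
                        peak_rate = 15, baseline_rate = 0.1)
  r <- neuron_rate(traj, hd_nrn)
  expect_gt(stats::cor(r, exp(6 * (cos((traj$hd_deg - 90) * pi / 180) - 1))), 0.999)
})

test_that("phase-precessing spikes precess at the stated slope", {
  run <- fx_straight_run(speed = 20, duration = 5)
  nrn <- neuron_spec("phase_precessing", center = c(50, 50), sigma = 10,
                     peak_rate = 40, baseline_rate = 0,
                     precession_slope = -8, theta_rate = 8)
  st <- simulate_spikes(run, nrn, seed = 3, phase_noise_deg = 5)
  expect_false(is.null(st$theta_peaks))
  expect_equal(diff(st$theta_peaks), rep(1 / 8, length(st$theta_peaks) - 1))
  ph <- assign_theta_phase(st$times, st$theta_peaks)
  x <- 20 * ph$spike_times           # position of an eastward run
  infield <- abs(x - 50) < 10
  fit <- fit_phase_precession(ph$phase_deg[infield], x[infield])
  expect_lt(fit$slope, 0)
  expect_lt(abs(fit$slope - (-8)), 2)
})

test_that("sample_empirical_ifis resamples the pool with replacement", {
  expect_equal(sample_empirical_ifis(1 / 30, 5, seed = 1), rep(1 / 30, 5))
  pool <- commercial_ifi_pool(n = 5000, rate = 25, seed = 2)
  s1 <- sample_empirical_ifis(pool, 5000, seed = 7)
  s2 <- sample_empirical_ifis(pool, 5000, seed = 7)
  expect_identical(s1, s2)
  se <- stats::sd(pool) / sqrt(5000)
  expect_lt(abs(mean(s1) - mean(pool)), 3 * se)
  expect_true(all(s1 %in% pool))
  expect_error(sample_empirical_ifis(numeric(0), 3, seed = 1), "nonempty")
})

test_that("IFI pools match their published summary statistics", {
  com <- commercial_ifi_pool(n = 20000, rate = 25, seed = 1)
  dev <- (com - 1 / 25) * 1000 # ms
  expect_true(all(abs(dev) <= 7))
  expect_lt(abs(mean(abs(dev) > 1) - 0.4), 0.02)
  pico <- picamera_ifi_pool(n = 20000, rate = 30, seed = 1)
  expect_true(all(abs(pico - 1 / 30) <= 0.025 / 1000))
})

test_that("session directory round trip preserves timestamps and frames", {
  arena <- arena_spec(100, 100)
  cams <- list(overhead_camera(0, 0, 120, 90, image_size = c(120L, 90L),
                               frame_rate = 5, clock_offset = 0.25,
                               clock_drift = 1e-5, id = 1L),
               overhead_camera(20, 0, 120, 90, image_size = c(120L, 90L),
                               frame_rate = 5, id = 2L))
  traj <- simulate_trajectory(arena, 2, 10, seed = 5)
  sess <- render_session(traj, cams, arena, seed = 6)
  ttl <- generate_ttl_logs(cams, 2, period = 1)
  dir <- withr::local_tempdir()
  write_session(sess, ttl, dir, write_frames = TRUE, max_frames = 2)
  rt <- read_session_dir(dir)
  expect_length(rt$timestamps, 2)
  expect_equal(rt$timestamps[[1]]$times, sess[[1]]$timestamps$times)
  expect_equal(rt$ttl_device[[1]]$time_s, ttl$device[[1]]$time_s)
  expect_equal(rt$ttl_daq$time_s, ttl$daq$time_s)
  img <- read_frame_png(rt$frame_files[[1]][1])
  expect_equal(img, sess[[1]]$frame(1), tolerance = 1e-8)
  # TTL logs: alternating states through each camera's clock model
  expect_equal(ttl$device[[1]]$time_s, 0.25 + (1 + 1e-5) * ttl$daq$time_s)
  expect_true(all(abs(diff(ttl$daq$state)) == 1))
})
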