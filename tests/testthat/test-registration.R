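# Homography primitives, feature matching, RANSAC, canvas construction and
# projection-error QC.

test_that("homography fit and warp round trips", {
  H0 <- matrix(c(1.1, 0.05, 12, -0.04, 0.95, -7, 1e-4, -5e-5, 1), 3, 3,
               byrow = TRUE)
  src <- withr::with_seed(1, matrix(runif(200, 0, 300), ncol = 2))
  dst <- apply_homography(H0, src)
  H <- fit_homography(src, dst)
  expect_lt(rel_h_error(H, H0), 1e-9)
  # warp then inverse-warp returns the input
  reg <- camera_registration(1L, H0)
  back <- warp_point(warp_point(src, reg), reg, inverse = TRUE)
  expect_lt(max(abs(back - src)), 1e-6)
  # identity and pure scale
  reg_id <- camera_registration(1L, diag(3))
  expect_equal(warp_point(c(5, 7), reg_id), cbind(5, 7))
  reg_s <- camera_registration(1L, diag(c(3, 3, 1)))
  expect_equal(warp_point(c(5, 7), reg_s), cbind(15, 21))
  # points mapping to infinity are flagged
  Hdeg <- diag(3); Hdeg[3, ] <- c(-1, 0, 10)
  expect_warning(out <- apply_homography(Hdeg, c(10, 3)), "infinity")
  expect_true(all(is.na(out)))
  expect_error(fit_homography(src[1:3, ], dst[1:3, ]), ">= 4")
})

test_that("match_features recovers known transforms", {
  scene <- fx_two_cam_scene()
  f1 <- scene$frames[[1]]
  m_same <- match_features(f1, f1)
  expect_gt(nrow(m_same), 10)
  expect_lt(max(abs(m_same$ax - m_same$bx)), 1e-6)
  expect_lt(max(abs(m_same$ay - m_same$by)), 1e-6)
  # pure 10-px translation
  f_shift <- cbind(f1[, 11:ncol(f1)], matrix(0, nrow(f1), 10))
  m_tr <- match_features(f1, f_shift)
  expect_gt(nrow(m_tr), 10)
  expect_lt(stats::median(abs(m_tr$ax - 10 - m_tr$bx)), 1)
  expect_lt(stats::median(abs(m_tr$ay - m_tr$by)), 1)
  # matches across the two cameras agree with ground-truth projections
  m12 <- match_features(scene$frames[[1]], scene$frames[[2]])
  expect_true(attr(m12, "registrable"))
  pr <- scene$projections
  p1 <- pr[pr$camera == 1, ]; p2 <- pr[pr$camera == 2, ]
  good <- 0L
  for (k in seq_len(nrow(m12))) {
    fi <- which.min((p1$px_x - m12$ax[k])^2 + (p1$px_y - m12$ay[k])^2)
    d <- sqrt((p2$px_x[fi] - m12$bx[k])^2 + (p2$px_y[fi] - m12$by[k])^2)
    if (d < 2) good <- good + 1L
  }
  expect_gte(good / nrow(m12), 0.8)
})

test_that("RANSAC recovers homographies and rejects planted outliers", {
  corr_id <- correspondence_set(cbind(c(1, 50, 50, 99, 30), c(1, 2, 80, 99, 40)),
                                cbind(c(1, 50, 50, 99, 30), c(1, 2, 80, 99, 40)))
  fit_id <- estimate_homography_ransac(corr_id, seed = 1)
  expect_lt(rel_h_error(fit_id$H, diag(3)), 1e-9)
  expect_true(all(fit_id$inliers))
  H0 <- matrix(c(0.9, 0.1, 5, -0.08, 1.05, 3, 5e-5, 1e-4, 1), 3, 3, byrow = TRUE)
  pts <- withr::with_seed(2, matrix(runif(120, 0, 200), ncol = 2))
  clean <- apply_homography(H0, pts)
  fit0 <- estimate_homography_ransac(correspondence_set(pts, clean), seed = 3)
  expect_lt(rel_h_error(fit0$H, H0), 1e-6)
  # 70% inliers + 30% uniform outliers
  n_out <- 26L
  dirty <- clean
  dirty[1:n_out, ] <- withr::with_seed(4, matrix(runif(2 * n_out, 0, 200), ncol = 2))
  fit <- estimate_homography_ransac(correspondence_set(pts, dirty),
                                    inlier_threshold = 2, seed = 5)
  expect_true(all(!fit$inliers[1:n_out]))
  expect_true(all(fit$inliers[(n_out + 1):60]))
  oracle <- fit_homography(pts[(n_out + 1):60, ], clean[(n_out + 1):60, ])
  expect_lt(rel_h_error(fit$H, oracle), 1e-9)
  expect_error(estimate_homography_ransac(correspondence_set(pts[1:3, ],
                                                             clean[1:3, ])),
               "at least 4")
})

test_that("RANSAC recovery holds across seeds and outlier fractions", {
  H0 <- matrix(c(1.05, -0.03, 8, 0.02, 0.97, -4, 2e-5, -4e-5, 1), 3, 3,
               byrow = TRUE)
  pts <- withr::with_seed(6, matrix(runif(160, 0, 250), ncol = 2))
  clean <- apply_homography(H0, pts)
  for (s in 1:20) {
    dirty <- clean
    n_out <- 40L # 50% outliers
    dirty[1:n_out, ] <- withr::with_seed(100 + s,
                          matrix(runif(2 * n_out, 0, 250), ncol = 2))
    fit <- estimate_homography_ransac(correspondence_set(pts, dirty),
                                      inlier_threshold = 1, seed = s)
    expect_lt(rel_h_error(fit$H, H0), 1e-6)
  }
})

test_that("build_canvas chains cameras onto one metric canvas", {
  # single camera: canvas is its own image plane scaled to cm
  one <- build_canvas(NULL, cm_per_px = 0.5, image_sizes = list(c(100L, 80L)),
                      pair_matches = list())
  expect_length(one, 1)
  p <- warp_point(c(10, 10), one[[1]])
  q <- warp_point(c(30, 10), one[[1]])
  expect_equal(sqrt(sum((q - p)^2)), 10) # 20 px * 0.5 cm/px
  # two cameras under pure translation, ground-truth matches
  cams <- fx_two_cams()
  pm <- list("1-2" = gt_pair_matches(cams[[1]], cams[[2]], spacing = 8))
  regs <- build_canvas(NULL, ref_camera = 1, cm_per_px = 0.5,
                       pair_matches = pm,
                       image_sizes = lapply(cams, function(c) c$image_size))
  # both cameras map shared canvas-truth points to the same spot
  pts <- as.matrix(expand.grid(x = seq(65, 110, by = 5), y = seq(20, 70, by = 5)))
  w1 <- warp_point(apply_homography(cams[[1]]$H, pts), regs[[1]])
  w2 <- warp_point(apply_homography(cams[[2]]$H, pts), regs[[2]])
  expect_lt(max(sqrt(rowSums((w1 - w2)^2))), 1e-6)
  expect_true(all(regs[[1]]$canvas_bounds[c("xmin", "ymin")] == 0))
  # landmark-based scale: two truth points a known distance apart
  lp <- apply_homography(cams[[1]]$H, rbind(c(30, 30), c(90, 30)))
  regs_lm <- build_canvas(NULL, ref_camera = 1,
                          landmark = list(camera = 1, p1 = lp[1, ], p2 = lp[2, ],
                                          distance_cm = 60),
                          pair_matches = pm,
                          image_sizes = lapply(cams, function(c) c$image_size))
  lw <- warp_point(lp, regs_lm[[1]])
  expect_equal(sqrt(sum((lw[2, ] - lw[1, ])^2)), 60, tolerance = 1e-6)
  expect_error(build_canvas(NULL, pair_matches = list(),
                            image_sizes = list(c(10L, 10L), c(10L, 10L))),
               "disconnected")
})

test_that("a 2x2 rig registers from its calibration scene", {
  rig <- make_camera_rig(arena_spec(100, 100), nx = 2, ny = 2,
                         overlap_frac = 0.5, image_size = c(160L, 120L),
                         rotations = c(0, 1, -1, 2))
  scene <- generate_calibration_scene(rig, n_features = 150, seed = 8)
  regs <- build_canvas(scene$frames, ref_camera = 1, cm_per_px = 1, seed = 8)
  pr <- scene$projections[scene$projections$visible, ]
  canvas_pts <- lapply(split(pr, pr$feature), function(g) {
    if (nrow(g) < 2) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(g)), function(i)
      warp_point(c(g$px_x[i], g$px_y[i]), regs[[g$camera[i]]])))
  })
  spread <- vapply(Filter(Negate(is.null), canvas_pts), function(m)
    max(sqrt(rowSums(sweep(m, 2, colMeans(m))^2))), numeric(1))
  # shared features land on one canvas point: typical agreement well under
  # a pixel, worst case bounded by the RANSAC inlier budget (2 px)
  expect_lt(stats::median(spread) * regs[[1]]$cm_per_px, 0.5)
  expect_lt(max(spread) * regs[[1]]$cm_per_px, 2)
})

test_that("build_canvas is reference-invariant up to canvas similarity", {
  cams <- fx_two_cams()
  pm <- list("1-2" = gt_pair_matches(cams[[1]], cams[[2]], spacing = 8))
  sizes <- lapply(cams, function(c) c$image_size)
  grid <- expand.grid(x = seq(70, 110, by = 10), y = seq(25, 65, by = 10))
  pts <- do.call(rbind, lapply(1:2, function(ci) {
    px <- apply_homography(cams[[ci]]$H, as.matrix(grid))
    data.frame(intersection = seq_len(nrow(grid)), camera = ci,
               px_x = px[, 1], px_y = px[, 2])
  }))
  e1 <- projection_error(pts, build_canvas(NULL, ref_camera = 1, cm_per_px = 0.5,
                                           pair_matches = pm, image_sizes = sizes))
  e2 <- projection_error(pts, build_canvas(NULL, ref_camera = 2, cm_per_px = 0.5,
                                           pair_matches = pm, image_sizes = sizes))
  expect_lt(max(abs(e1$errors$error_cm - e2$errors$error_cm)), 1e-6)
})

test_that("projection_error is distance to the mean observed position", {
  regs <- list(camera_registration(1L, diag(3)),
               camera_registration(2L, similarity_transform(1, 1, 0)))
  pts <- data.frame(intersection = c(1, 1, 2), camera = c(1L, 2L, 1L),
                    px_x = c(10, 10, 5), px_y = c(10, 10, 5))
  # camera 2's warp shifts x by +1 cm: both errors are 0.5 cm
  rep <- projection_error(pts, regs)
  expect_equal(rep$errors$error_cm, c(0.5, 0.5))
  expect_equal(rep$skipped, 2)
  expect_equal(rep$overall_median_cm, 0.5)
  # exact agreement gives zero error
  regs0 <- list(camera_registration(1L, diag(3)), camera_registration(2L, diag(3)))
  rep0 <- projection_error(pts[1:2, ], regs0)
  expect_equal(rep0$errors$error_cm, c(0, 0))
  expect_error(projection_error(pts[3, , drop = FALSE], regs), ">= 2")
})

test_that("registrations survive a JSON round trip", {
  cams <- fx_two_cams()
  pm <- list("1-2" = gt_pair_matches(cams[[1]], cams[[2]], spacing = 8))
  regs <- build_canvas(NULL, cm_per_px = 0.5, pair_matches = pm,
                       image_sizes = lapply(cams, function(c) c$image_size))
  path <- withr::local_tempfile(fileext = ".json")
  write_registrations(regs, path)
  back <- read_registrations(path)
  expect_length(back, 2)
  expect_equal(back[[2]]$H, regs[[2]]$H)
  expect_equal(back[[1]]$cm_per_px, regs[[1]]$cm_per_px)
  expect_equal(unname(back[[1]]$canvas_bounds),
               unname(regs[[1]]$canvas_bounds))
})
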