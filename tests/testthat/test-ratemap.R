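# Rate maps, smoothing, adaptive binning, spatial information, place-field
# segmentation and the cyclic shuffle test.

test_that("compute_rate_map divides spikes by dwell after filters", {
  # single bin visited 10 s with 20 spikes -> 2 Hz
  t <- seq(0, 10, by = 0.1)
  sess <- manual_session(t, 1, 1, speed = 5)
  spikes <- seq(0.2, 9.8, length.out = 20)
  m <- compute_rate_map(sess, spikes, bin_size = 2)
  expect_equal(sum(m$valid), 1L)
  expect_equal(m$rate[m$valid], 20 / sum(m$occupancy), tolerance = 1e-9)
  expect_equal(m$rate[m$valid], 2, tolerance = 0.02) # dwell ~ 10 s
  # all motion below the speed filter -> error
  slow <- manual_session(t, 1, 1, speed = 1)
  expect_error(compute_rate_map(slow, spikes, bin_size = 2), "speed filter")
  # spikes during slow samples are excluded (conservation invariant)
  sess2 <- fx_study_session()
  sp2 <- fx_place_spikes()$times
  m2 <- compute_rate_map(sess2, sp2, bin_size = 2)
  ok <- sess2$speed_cms >= 2
  si <- vapply(sp2, function(s) which.min(abs(sess2$time_s - s)), integer(1))
  in_valid <- m2$occupancy[cbind(
    findInterval(sess2$x_cm[si], m2$x_edges, rightmost.closed = TRUE, all.inside = TRUE),
    findInterval(sess2$y_cm[si], m2$y_edges, rightmost.closed = TRUE, all.inside = TRUE))] >=
    0.4 - 1e-9 # same roundoff guard as the validity rule
  expect_equal(m2$n_spikes_used, sum(ok[si] & in_valid))
})

test_that("rate errors on synthetic cells stay within Poisson bounds", {
  sess <- fx_study_session()
  st <- fx_place_spikes()
  m <- smooth_map_gaussian(compute_rate_map(sess, st$times, bin_size = 2))
  # peak of the smoothed map sits near the true field centre
  peak <- which(m$rate == m$peak_rate, arr.ind = TRUE)[1, ]
  px <- (m$x_edges[peak[1]] + m$x_edges[peak[1] + 1]) / 2
  py <- (m$y_edges[peak[2]] + m$y_edges[peak[2] + 1]) / 2
  expect_lt(sqrt((px - 40)^2 + (py - 60)^2), 6)
  expect_lt(abs(m$peak_rate - 12.1) / 12.1, 0.35)
})

test_that("smooth_map_gaussian is mask-normalized", {
  # constant map with holes stays constant
  occ <- matrix(1, 8, 8)
  rate <- matrix(3, 8, 8)
  valid <- matrix(TRUE, 8, 8); valid[3, 4] <- FALSE
  m <- manual_rate_map(rate, occ, valid = valid)
  sm <- smooth_map_gaussian(m, sigma = 1.25)
  expect_equal(sm$rate[valid], rep(3, sum(valid)))
  expect_true(is.na(sm$rate[3, 4]))
  expect_equal(sm$peak_rate, 3)
  # impulse: kernel mass conserved when fully valid and away from edges
  # (kernel radius is ceiling(3 * sigma) = 4 bins at sigma = 1.25)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 10
  smi <- smooth_map_gaussian(manual_rate_map(imp, matrix(1, 21, 21)), 1.25)
  expect_equal(sum(smi$rate), 10, tolerance = 1e-9)
  k <- exp(-(-4:4)^2 / (2 * 1.25^2)); k <- k / sum(k)
  expect_equal(smi$rate[11, 7:15], 10 * k[5] * k, tolerance = 1e-9)
  # half-masked map: valid-side values match the 1D renormalized expectation
  hv <- matrix(rep(c(TRUE, FALSE), each = 9), 9, 2) # column 1 valid only
  hr <- matrix(rep(c(2, 0), each = 9), 9, 2)
  smh <- smooth_map_gaussian(manual_rate_map(hr, matrix(1, 9, 2), valid = hv), 1.25)
  expect_equal(smh$rate[5, 1], 2, tolerance = 1e-9)
})

test_that("adaptive binning approaches the right limits", {
  sess <- fx_study_session()
  st <- fx_place_spikes()
  raw <- compute_rate_map(sess, st$times, bin_size = 4)
  # zero spikes: radius hits the cap, all rates 0
  none <- compute_rate_map(sess, numeric(0), bin_size = 4)
  ad0 <- adaptive_smooth(none, sess)
  expect_true(all(ad0$rate[ad0$valid] == 0))
  # enormous alpha: every bin's circle covers the whole map -> global mean
  ad_inf <- adaptive_smooth(raw, sess, alpha = 1e18)
  gm <- sum(raw$spikes[raw$occupancy > 0]) / sum(raw$occupancy[raw$occupancy > 0])
  expect_lt(max(abs(ad_inf$rate[ad_inf$valid] - gm)), 1e-9)
  # default alpha keeps the adaptive map close to the raw map where data
  # are dense (interior, well-sampled bins)
  ad <- adaptive_rate_map(sess, st$times, bin_size = 4)
  dense <- raw$valid & raw$occupancy > stats::quantile(raw$occupancy[raw$valid], 0.75)
  relerr <- abs(ad$rate[dense] - raw$rate[dense]) /
    pmax(raw$rate[dense], gm)
  expect_lt(stats::median(relerr), 0.2)
})

test_that("spatial_information matches the Skaggs formula", {
  uni <- manual_rate_map(matrix(4.2, 6, 6), matrix(0.7, 6, 6))
  expect_lt(abs(spatial_information(uni)), 1e-12)
  four <- manual_rate_map(matrix(c(8, 0, 0, 0), 2, 2), matrix(1, 2, 2))
  expect_equal(spatial_information(four), 2)
  two <- manual_rate_map(matrix(c(2, 0), 1, 2), matrix(c(5, 5), 1, 2))
  expect_equal(spatial_information(two), 1)
  dead <- manual_rate_map(matrix(0, 3, 3), matrix(1, 3, 3))
  expect_warning(i0 <- spatial_information(dead), "zero")
  expect_true(is.na(i0))
  # non-negative on arbitrary maps
  arb <- manual_rate_map(matrix(withr::with_seed(2, rexp(64)), 8, 8),
                         matrix(withr::with_seed(3, runif(64, 0.4, 2)), 8, 8))
  expect_gte(spatial_information(arb), 0)
})

test_that("detect_place_fields applies the 7-bin / 15% / 25% rules", {
  # single Gaussian bump well above floor
  g <- outer(1:15, 1:15, function(i, j) 10 * exp(-((i - 8)^2 + (j - 8)^2) / 8))
  occ <- matrix(1, 15, 15)
  sm <- smooth_map_gaussian(manual_rate_map(g, occ), 1.25)
  f1 <- detect_place_fields(sm)
  expect_length(f1, 1)
  expect_true(which.max(sm$rate) %in% f1[[1]]$bins)
  # suprathreshold support of 6 bins -> no field
  tiny <- matrix(0.01, 9, 9)
  tiny[4:5, 4:6] <- 10 # 6 bins above 15% of 10
  f2 <- detect_place_fields(manual_rate_map(tiny, matrix(1, 9, 9)))
  expect_length(f2, 0)
  # second bump at 2 Hz is below 25% of the 10 Hz map peak
  two <- matrix(0.01, 20, 10)
  two[3:6, 3:6] <- 10
  two[14:17, 3:6] <- 2
  f3 <- detect_place_fields(manual_rate_map(two, matrix(1, 20, 10)))
  expect_length(f3, 1)
  expect_equal(f3[[1]]$peak_rate, 10)
  expect_equal(f3[[1]]$size, 16L)
  # invariance to positive scaling
  f3b <- detect_place_fields(manual_rate_map(two * 37, matrix(1, 20, 10)))
  expect_equal(lapply(f3b, function(f) f$bins), lapply(f3, function(f) f$bins))
  # two comparable bumps give two fields, sizes descending
  twin <- matrix(0.01, 20, 10)
  twin[2:7, 3:6] <- 8
  twin[13:16, 3:6] <- 9
  f4 <- detect_place_fields(manual_rate_map(twin, matrix(1, 20, 10)))
  expect_length(f4, 2)
  expect_gte(f4[[1]]$size, f4[[2]]$size)
})

test_that("place-field centres recover the generator ground truth", {
  sess <- fx_study_session()
  st <- fx_place_spikes()
  # 4-cm bins: at 2 cm too many near-centre bins fail the 0.4 s occupancy
  # rule in a 1200 s session, so footprint containment is only a fair claim
  # at the coarser bin size
  sm <- smooth_map_gaussian(compute_rate_map(sess, st$times, bin_size = 4))
  fields <- detect_place_fields(sm)
  expect_gte(length(fields), 1)
  expect_gte(fields[[1]]$size, 7)
  nx <- nrow(sm$rate)
  bx <- ((fields[[1]]$bins - 1) %% nx) + 1
  by <- ((fields[[1]]$bins - 1) %/% nx) + 1
  cx <- (sm$x_edges[bx] + sm$x_edges[bx + 1]) / 2
  cy <- (sm$y_edges[by] + sm$y_edges[by + 1]) / 2
  # true centre (40, 60) lies inside the detected field footprint
  expect_lt(min(sqrt((cx - 40)^2 + (cy - 60)^2)), 2 * sqrt(2))
})

test_that("shuffle_significance flags a real place cell and validates input", {
  sess <- fx_study_session()
  st <- fx_place_spikes()
  res <- shuffle_significance(sess, st$times, bin_size = 2,
                              n_shuffles = 1000, seed = 2)
  expect_lte(res$p_value, 0.001)
  expect_true(res$significant)
  expect_length(res$null, 1000)
  expect_gt(res$observed, stats::quantile(res$null, 0.999))
  expect_error(shuffle_significance(sess, st$times, n_shuffles = 0), "n_shuffles")
  short <- manual_session(seq(0, 50, by = 0.1), 1, 1, speed = 5)
  expect_error(shuffle_significance(short, c(1, 2), margin = 30), "margin")
  # raw and adaptive scorers agree on the verdict for a strong cell
  res_ad <- shuffle_significance(sess, st$times, bin_size = 2,
                                 n_shuffles = 20, seed = 2, method = "adaptive")
  expect_lte(res_ad$p_value, 0.05)
})

test_that("the vectorized raw shuffle null matches per-shift recomputation", {
  sess <- fx_study_session()
  st <- fx_place_spikes()
  res <- shuffle_significance(sess, st$times, bin_size = 4, n_shuffles = 5,
                              seed = 7)
  t <- sess$time_s
  T_span <- t[length(t)] - t[1]
  shifts <- withr::with_seed(7L, stats::runif(5, 30, T_span - 30))
  manual <- vapply(shifts, function(sh) {
    sp2 <- t[1] + ((st$times - t[1] + sh) %% T_span)
    spatial_information(compute_rate_map(sess, sp2, bin_size = 4))
  }, numeric(1))
  expect_equal(res$null, manual, tolerance = 1e-12)
})
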