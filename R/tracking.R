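# Two-LED position tracking: per-camera intensity thresholding and HSV
# colour segmentation, centroid extraction, canvas merging across cameras,
# head direction and running speed.

#' HSV colour range
#'
#' Hue is on the 0-180 scale and may be a union of two intervals (red wraps
#' around 0); saturation and value are on 0-255.
#'
#' @param h list of hue intervals, each c(lo, hi) within [0, 180].
#' @param s,v saturation / value intervals c(lo, hi) within [0, 255].
#' @return object of class `hsv_range`.
#' @export
hsv_range <- function(h, s, v) {
  if (!is.list(h)) h <- list(h)
  for (iv in c(h, list(s, v))) stopifnot(length(iv) == 2, iv[1] <= iv[2])
  for (iv in h) if (iv[1] < 0 || iv[2] > 180) abort("hue interval outside 0..180")
  for (iv in list(s, v)) if (iv[1] < 0 || iv[2] > 255) abort("S/V interval outside 0..255")
  structure(list(h = h, s = s, v = v), class = "hsv_range")
}

#' Default LED colour ranges
#'
#' Red: H 0:10 or 160:180, S 100:255, V 50:255. Green: H 50:70, S 50:255,
#' V 100:255 (hue on the 0-180 scale).
#' @return an `hsv_range`.
#' @export
red_led_range <- function() hsv_range(list(c(0, 10), c(160, 180)), c(100, 255), c(50, 255))

#' @rdname red_led_range
#' @export
green_led_range <- function() hsv_range(list(c(50, 70)), c(50, 255), c(100, 255))

#' Detect the red and green LEDs in one colour frame
#'
#' Pixels whose maximum channel reaches `intensity_threshold` are converted
#' to HSV and masked by each LED's colour range; the centroid of the largest
#' connected component (8-connectivity) of each mask is the LED position.
#' Components smaller than `min_pixels` count as absent.
#'
#' @param frame numeric array [rows, cols, 3], values 0..255.
#' @param intensity_threshold candidate-pixel threshold on the max channel.
#' @param red,green [hsv_range()]s for the two LEDs.
#' @param min_pixels minimum cluster size, pixels.
#' @return list with `red` and `green`, each a list `present`, `centroid`
#'   (c(x, y) pixels, NA when absent) and `n_pixels`.
#' @export
detect_leds <- function(frame, intensity_threshold = 50,
                        red = red_led_range(), green = green_led_range(),
                        min_pixels = 3) {
  stopifnot(length(dim(frame)) == 3, dim(frame)[3] == 3)
  nr <- dim(frame)[1]; nc <- dim(frame)[2]
  mx <- pmax(frame[, , 1], frame[, , 2], frame[, , 3])
  cand <- which(mx >= intensity_threshold)
  absent <- list(present = FALSE, centroid = c(NA_real_, NA_real_), n_pixels = 0L)
  if (length(cand) == 0) return(list(red = absent, green = absent))
  r <- frame[, , 1][cand]; g <- frame[, , 2][cand]; b <- frame[, , 3][cand]
  hsv <- grDevices::rgb2hsv(r, g, b, maxColorValue = 255)
  h <- hsv[1, ] * 180; s <- hsv[2, ] * 255; v <- hsv[3, ] * 255
  one_color <- function(range) {
    in_h <- Reduce(`|`, lapply(range$h, function(iv) h >= iv[1] & h <= iv[2]))
    sel <- in_h & s >= range$s[1] & s <= range$s[2] & v >= range$v[1] & v <= range$v[2]
    if (!any(sel)) return(absent)
    mask <- matrix(FALSE, nr, nc)
    mask[cand[sel]] <- TRUE
    lab <- label_components(mask, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    big <- which.max(sizes)
    if (sizes[big] < min_pixels) return(absent)
    idx <- which(lab == big)
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    list(present = TRUE, centroid = c(mean(cols), mean(rows)),
         n_pixels = sizes[big])
  }
  list(red = one_color(red), green = one_color(green))
}

#' Merge per-camera LED detections on the canvas
#'
#' Each camera's pixel centroid is warped into canvas cm; the merged position
#' is the arithmetic mean over the cameras where the LED is present. Absent
#' everywhere gives NA.
#'
#' @param detections list (one per camera) of [detect_leds()] results (or
#'   NULL for cameras with no frame at this time).
#' @param regs list of [camera_registration()] matching `detections`.
#' @return list with `red`, `green` (each c(x, y) cm or c(NA, NA)), `n_red`,
#'   `n_green` (contributing camera counts).
#' @export
merge_positions <- function(detections, regs) {
  stopifnot(length(detections) == length(regs))
  merge_one <- function(color) {
    pts <- NULL
    for (ci in seq_along(detections)) {
      d <- detections[[ci]][[color]]
      if (is.null(d) || !isTRUE(d$present)) next
      pts <- rbind(pts, warp_point(d$centroid, regs[[ci]]))
    }
    if (is.null(pts)) list(pos = c(NA_real_, NA_real_), n = 0L)
    else list(pos = colMeans(pts), n = nrow(pts))
  }
  r <- merge_one("red"); g <- merge_one("green")
  list(red = r$pos, green = g$pos, n_red = r$n, n_green = g$n)
}

#' Head direction from the two LED positions
#'
#' Angle of the vector from the posterior green LED to the anterior red LED,
#' counterclockwise from the +x axis, degrees in [0, 360). Coincident LEDs
#' give NA.
#'
#' @param red,green positions c(x, y) in canvas cm (vectors or n x 2
#'   matrices).
#' @return numeric head direction(s), degrees.
#' @export
head_direction <- function(red, green) {
  if (is.null(dim(red))) red <- matrix(red, ncol = 2)
  if (is.null(dim(green))) green <- matrix(green, ncol = 2)
  dx <- red[, 1] - green[, 1]; dy <- red[, 2] - green[, 2]
  out <- wrap_deg(atan2(dy, dx) * 180 / pi)
  out[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  out
}

#' Running speed from tracked positions
#'
#' Central-difference displacement over time, then boxcar smoothing. Missing
#' positions propagate to missing speed.
#'
#' @param times frame times, s.
#' @param x,y positions, cm (NA allowed).
#' @param window boxcar smoothing window, frames (1 = none).
#' @return numeric speed, cm/s.
#' @export
compute_speed <- function(times, x, y, window = 5) {
  n <- length(times)
  if (n < 2) abort("need at least 2 tracked frames")
  sp <- rep(NA_real_, n)
  if (n >= 3) {
    i <- 2:(n - 1)
    sp[i] <- sqrt((x[i + 1] - x[i - 1])^2 + (y[i + 1] - y[i - 1])^2) /
      (times[i + 1] - times[i - 1])
  }
  sp[1] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) / (times[2] - times[1])
  sp[n] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) / (times[n] - times[n - 1])
  if (window > 1) {
    k <- rep(1 / window, window)
    sm <- stats::filter(sp, k, sides = 2)
    sp <- ifelse(is.na(sm), sp, as.numeric(sm))
  }
  sp
}

#' Assemble a tracked session from per-frame fields
#'
#' @param times acquisition-clock frame times, s.
#' @param red,green,position n x 2 matrices of canvas positions, cm.
#' @param hd_deg head direction, degrees.
#' @param speed_cms running speed, cm/s.
#' @param n_cameras contributing camera count per frame.
#' @return object of class `tracked_session` (a data.frame with columns
#'   `time_s`, `red_x_cm`, `red_y_cm`, `green_x_cm`, `green_y_cm`, `x_cm`,
#'   `y_cm`, `hd_deg`, `speed_cms`, `n_cameras`).
#' @export
tracked_session <- function(times, red, green, position, hd_deg, speed_cms,
                            n_cameras) {
  df <- data.frame(time_s = times,
                   red_x_cm = red[, 1], red_y_cm = red[, 2],
                   green_x_cm = green[, 1], green_y_cm = green[, 2],
                   x_cm = position[, 1], y_cm = position[, 2],
                   hd_deg = hd_deg, speed_cms = speed_cms,
                   n_cameras = n_cameras)
  class(df) <- c("tracked_session", "data.frame")
  df
}

#' Track a rendered session end to end
#'
#' For every frame of the reference timeline (the camera with the earliest
#' aligned first frame): associate each camera's nearest aligned frame within
#' half an expected IFI, detect both LEDs per camera, warp the centroids to
#' the canvas, average across cameras, then derive the head-centre position
#' (red/green midpoint by default), head direction and speed. Gaps where an
#' LED was seen nowhere are linearly interpolated up to `max_gap` frames
#' (set 0 to disable).
#'
#' @param session a [render_session()] result (frames + device timestamps).
#' @param regs list of [camera_registration()], one per camera.
#' @param clock_maps optional list of [build_clock_map()] per camera; when
#'   given, device timestamps are aligned to the acquisition clock first.
#' @param intensity_threshold,red,green passed to [detect_leds()].
#' @param max_gap maximum gap length to interpolate, frames.
#' @param position which tracked point stands for the animal: red/green
#'   midpoint (default) or a single LED.
#' @param speed_window boxcar window for [compute_speed()].
#' @return a [tracked_session()].
#' @export
track_session <- function(session, regs, clock_maps = NULL,
                          intensity_threshold = 50,
                          red = red_led_range(), green = green_led_range(),
                          max_gap = 5,
                          position = c("midpoint", "red", "green"),
                          speed_window = 5) {
  stopifnot(inherits(session, "rendered_session"))
  position <- match.arg(position)
  n_cam <- length(session)
  if (n_cam == 0 || length(session[[1]]$timestamps$times) == 0)
    abort("session has no frames")
  aligned <- lapply(seq_len(n_cam), function(ci) {
    ts <- session[[ci]]$timestamps
    if (!is.null(clock_maps)) align_timestamps(ts, clock_maps[[ci]]) else ts
  })
  ref <- which.min(vapply(aligned, function(a) a$times[1], numeric(1)))
  out_t <- aligned[[ref]]$times
  n_out <- length(out_t)
  half_ifi <- 0.5 / aligned[[ref]]$rate
  # per camera: index of the frame associated with each output time
  assoc <- lapply(seq_len(n_cam), function(ci) {
    tt <- aligned[[ci]]$times
    idx <- findInterval(out_t, tt)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(tt))
    pick <- ifelse(abs(tt[hi] - out_t) < abs(tt[lo] - out_t), hi, lo)
    pick[abs(tt[pick] - out_t) > half_ifi] <- NA_integer_
    pick
  })
  # detect once per used camera frame
  det_cache <- lapply(seq_len(n_cam), function(ci) {
    used <- sort(unique(assoc[[ci]][!is.na(assoc[[ci]])]))
    cache <- vector("list", length(session[[ci]]$acq_times))
    for (fi in used) {
      cache[[fi]] <- detect_leds(session[[ci]]$frame(fi),
                                 intensity_threshold, red, green)
    }
    cache
  })
  red_m <- matrix(NA_real_, n_out, 2)
  green_m <- matrix(NA_real_, n_out, 2)
  n_red <- integer(n_out); n_green <- integer(n_out)
  absent <- list(red = NULL, green = NULL)
  for (i in seq_len(n_out)) {
    dets <- lapply(seq_len(n_cam), function(ci) {
      fi <- assoc[[ci]][i]
      if (is.na(fi)) absent else det_cache[[ci]][[fi]]
    })
    m <- merge_positions(dets, regs)
    red_m[i, ] <- m$red; green_m[i, ] <- m$green
    n_red[i] <- m$n_red; n_green[i] <- m$n_green
  }
  if (max_gap > 0) {
    red_m <- interpolate_gaps(out_t, red_m, max_gap)
    green_m <- interpolate_gaps(out_t, green_m, max_gap)
  }
  pos <- switch(position,
                midpoint = (red_m + green_m) / 2,
                red = red_m, green = green_m)
  hd <- head_direction(red_m, green_m)
  sp <- compute_speed(out_t, pos[, 1], pos[, 2], window = speed_window)
  tracked_session(out_t, red_m, green_m, pos, hd, sp,
                  pmax(n_red, n_green))
}

#' @noRd
interpolate_gaps <- function(times, xy, max_gap) {
  ok <- !is.na(xy[, 1]) & !is.na(xy[, 2])
  if (sum(ok) < 2) return(xy)
  miss <- which(!ok)
  if (!length(miss)) return(xy)
  runs <- split(miss, cumsum(c(1, diff(miss) != 1)))
  for (run in runs) {
    if (length(run) > max_gap) next
    lo <- min(run) - 1L; hi <- max(run) + 1L
    if (lo < 1 || hi > nrow(xy)) next
    if (!ok[lo] || !ok[hi]) next
    w <- (times[run] - times[lo]) / (times[hi] - times[lo])
    xy[run, 1] <- xy[lo, 1] + w * (xy[hi, 1] - xy[lo, 1])
    xy[run, 2] <- xy[lo, 2] + w * (xy[hi, 2] - xy[lo, 2])
  }
  xy
}

#' Build an idealized tracked session directly from a trajectory
#'
#' Samples the ground-truth trajectory at the given acquisition-clock frame
#' times, bypassing rendering and detection. Used for timing-jitter
#' experiments where the quantity under study is the time-to-position
#' assignment, not the video pipeline.
#'
#' @param traj a `trajectory`.
#' @param frame_times acquisition-clock frame times, s.
#' @param led_geometry as in [render_session()].
#' @param speed_window boxcar window for [compute_speed()].
#' @return a [tracked_session()] with one contributing camera per frame.
#' @export
session_from_trajectory <- function(traj, frame_times,
                                    led_geometry = list(red_forward_cm = 2,
                                                        green_back_cm = 2),
                                    speed_window = 5) {
  samp <- sample_trajectory(traj, frame_times)
  u <- cbind(cos(samp$hd_deg * pi / 180), sin(samp$hd_deg * pi / 180))
  pos <- cbind(samp$x_cm, samp$y_cm)
  red <- pos + led_geometry$red_forward_cm * u
  green <- pos - led_geometry$green_back_cm * u
  sp <- compute_speed(frame_times, pos[, 1], pos[, 2], window = speed_window)
  tracked_session(frame_times, red, green, pos, samp$hd_deg, sp,
                  rep(1L, length(frame_times)))
}

#' Write / read a tracked session as CSV
#'
#' @param session a [tracked_session()].
#' @param path CSV path.
#' @return `write_tracking`: invisibly `path`; `read_tracking`: the session.
#' @export
write_tracking <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking
#' @export
read_tracking <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("tracked_session", "data.frame")
  df
}
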