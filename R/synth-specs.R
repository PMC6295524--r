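# Scene specifications for the synthetic-data generator: arena, cameras,
# occluders, neurons. All spatial quantities are in centimetres on the arena
# ("canvas") plane; image quantities are in pixels.

#' Arena specification
#'
#' Describes the rectangular floor of the behavioural arena, plus optional
#' occluders: boxes placed in the arena that hide the head LEDs from specific
#' cameras (all-or-none: a camera either sees the LED or does not).
#'
#' @param width,height arena extent in cm.
#' @param occluders list of occluder rectangles, each a list with `xmin`,
#'   `xmax`, `ymin`, `ymax` (cm) and `cameras` (integer ids of the cameras
#'   whose view of the LEDs the box blocks).
#' @return an object of class `arena_spec`.
#' @examples
#' arena_spec(100, 100)
#' @export
arena_spec <- function(width, height, occluders = list()) {
  if (!is_scalar_num(width) || width <= 0) abort("arena width must be > 0")
  if (!is_scalar_num(height) || height <= 0) abort("arena height must be > 0")
  for (oc in occluders) {
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "cameras") %in% names(oc)))
    if (oc$xmin < 0 || oc$xmax > width || oc$ymin < 0 || oc$ymax > height ||
        oc$xmin >= oc$xmax || oc$ymin >= oc$ymax)
      abort("occluder rectangle must lie inside the arena with positive area")
  }
  structure(list(width = width, height = height, occluders = occluders),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %.0f x %.0f cm, %d occluder(s)\n",
              x$width, x$height, length(x$occluders)))
  invisible(x)
}

#' Camera model
#'
#' One overhead camera with a ground-truth plane homography from arena
#' coordinates (cm) to image pixels, plus a clock model: constant offset,
#' linear drift and per-frame interframe-interval (IFI) jitter. The jitter
#' sampler is either `NULL` (ideal clock), a numeric pool of IFI deviations
#' (seconds, resampled with replacement) or a function `(n)` returning n
#' deviations.
#'
#' @param H_canvas_to_px 3x3 invertible homography, canvas cm -> image px.
#' @param image_size integer c(width, height) in pixels.
#' @param frame_rate nominal frame rate, Hz.
#' @param clock_offset device clock minus acquisition clock at t = 0, seconds.
#' @param clock_drift dimensionless drift rate: device time advances by
#'   (1 + clock_drift) seconds per acquisition second.
#' @param jitter IFI deviation sampler (see above), seconds.
#' @param drop_prob probability in [0, 1) that any given frame is dropped.
#' @param id camera identifier (integer or string).
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(H_canvas_to_px, image_size = c(640L, 480L),
                         frame_rate = 30, clock_offset = 0, clock_drift = 0,
                         jitter = NULL, drop_prob = 0, id = 1L) {
  stopifnot(is.matrix(H_canvas_to_px), all(dim(H_canvas_to_px) == c(3, 3)))
  if (abs(det(H_canvas_to_px)) < 1e-12) abort("camera homography must be invertible")
  if (!is_scalar_num(frame_rate) || frame_rate <= 0) abort("frame rate must be > 0")
  if (!is_scalar_num(drop_prob) || drop_prob < 0 || drop_prob >= 1)
    abort("drop_prob must be in [0, 1)")
  structure(list(
    id = id,
    H = H_canvas_to_px,
    H_inv = solve(H_canvas_to_px),
    image_size = as.integer(image_size),
    frame_rate = frame_rate,
    clock_offset = clock_offset,
    clock_drift = clock_drift,
    jitter = jitter,
    drop_prob = drop_prob
  ), class = "camera_model")
}

#' Build an overhead camera looking straight down at a floor patch
#'
#' Convenience constructor: the camera images the axis-aligned rectangle
#' `[x0, x0 + fov_w] x [y0, y0 + fov_h]` cm onto its full sensor, with an
#' optional in-plane rotation about the patch centre and a small projective
#' perspective term to emulate imperfect mounting.
#'
#' @param x0,y0 lower corner of the viewed floor patch, cm.
#' @param fov_w,fov_h extent of the viewed patch, cm.
#' @param rotation_deg in-plane rotation of the camera, degrees.
#' @param perspective length-2 numeric, the two projective entries of the
#'   homography (small values, e.g. 1e-4, tilt the image plane slightly).
#' @inheritParams camera_model
#' @return a `camera_model`.
#' @export
overhead_camera <- function(x0, y0, fov_w, fov_h, image_size = c(640L, 480L),
                            rotation_deg = 0, perspective = c(0, 0),
                            frame_rate = 30, clock_offset = 0, clock_drift = 0,
                            jitter = NULL, drop_prob = 0, id = 1L) {
  sx <- image_size[1] / fov_w
  sy <- image_size[2] / fov_h
  cx <- x0 + fov_w / 2; cy <- y0 + fov_h / 2
  th <- rotation_deg * pi / 180
  # rotate about patch centre, then scale to pixels with image centre fixed
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  T1 <- matrix(c(1, 0, -cx, 0, 1, -cy, 0, 0, 1), 3, 3, byrow = TRUE)
  S <- matrix(c(sx, 0, (image_size[1] + 1) / 2,
                0, sy, (image_size[2] + 1) / 2,
                0, 0, 1), 3, 3, byrow = TRUE)
  H <- S %*% R %*% T1
  H[3, 1:2] <- perspective
  H <- H / H[3, 3]
  camera_model(H, image_size = image_size, frame_rate = frame_rate,
               clock_offset = clock_offset, clock_drift = clock_drift,
               jitter = jitter, drop_prob = drop_prob, id = id)
}

#' Neuron specification for spike simulation
#'
#' @param kind `"place"`, `"head_direction"` or `"phase_precessing"`.
#' @param center place-field centre c(x, y) in cm (place / phase_precessing).
#' @param sigma place-field width (Gaussian SD), cm.
#' @param preferred_deg preferred head direction, degrees (head_direction).
#' @param kappa von Mises concentration of the direction tuning.
#' @param peak_rate tuning peak firing rate above baseline, Hz.
#' @param baseline_rate floor firing rate, Hz.
#' @param precession_slope phase change per cm traversed through the field,
#'   degrees/cm; negative for classic precession (phase_precessing only).
#' @param theta_rate theta rhythm frequency, Hz (phase_precessing only).
#' @return an object of class `neuron_spec`.
#' @export
neuron_spec <- function(kind = c("place", "head_direction", "phase_precessing"),
                        center = c(50, 50), sigma = 10,
                        preferred_deg = 0, kappa = 4,
                        peak_rate = 10, baseline_rate = 0.1,
                        precession_slope = -10, theta_rate = 8) {
  kind <- match.arg(kind)
  if (peak_rate < 0 || baseline_rate < 0) abort("rates must be >= 0")
  if (sigma <= 0) abort("sigma must be > 0")
  structure(list(kind = kind, center = center, sigma = sigma,
                 preferred_deg = wrap_deg(preferred_deg), kappa = kappa,
                 peak_rate = peak_rate, baseline_rate = baseline_rate,
                 precession_slope = precession_slope, theta_rate = theta_rate),
            class = "neuron_spec")
}

#' Is an arena point hidden from a given camera by any occluder?
#' @noRd
point_occluded <- function(arena, camera_id, x, y) {
  hidden <- rep(FALSE, length(x))
  for (oc in arena$occluders) {
    if (!(camera_id %in% oc$cameras)) next
    hidden <- hidden | (x >= oc$xmin & x <= oc$xmax & y >= oc$ymin & y <= oc$ymax)
  }
  hidden
}
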