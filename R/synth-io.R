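# On-disk session format: per camera a video (PNG frame stack), a
# `frametimes.csv` and a `ttl.csv`, plus shared `groundtruth.csv` and a YAML
# scene config — mirroring the file triple each recording subunit produces.

#' Generate synchronized TTL logs for a camera rig
#'
#' A shared square-wave TTL train (alternating on/off transitions) is logged
#' on the acquisition system and, through each camera's offset + drift clock,
#' on every camera device.
#'
#' @param cameras list of [camera_model()].
#' @param duration session length, seconds (acquisition clock).
#' @param period full on/off cycle period, seconds.
#' @return list with `daq` (data.frame `transition_index`, `state`, `time_s`
#'   on the acquisition clock) and `device` (list of per-camera data.frames of
#'   the same shape on each device clock).
#' @export
generate_ttl_logs <- function(cameras, duration, period = 1) {
  times <- seq(period / 2, duration, by = period / 2)
  if (length(times) == 0) abort("duration too short for any TTL transition")
  state <- rep_len(c(1L, 0L), length(times))
  daq <- data.frame(transition_index = seq_along(times), state = state,
                    time_s = times)
  device <- lapply(cameras, function(cam) {
    data.frame(transition_index = seq_along(times), state = state,
               time_s = cam$clock_offset + (1 + cam$clock_drift) * times)
  })
  list(daq = daq, device = device)
}

#' Write a rendered session to disk
#'
#' For each camera writes `camN/frame_%06d.png`, `camN/frametimes.csv`
#' (`frame_index`, `device_time_s`) and `camN/ttl.csv` (`transition_index`,
#' `state`, `device_time_s`); at the top level `ttl_daq.csv`,
#' `groundtruth.csv` (`time_s`, `x_cm`, `y_cm`, `hd_deg`) and `scene.yaml`.
#'
#' @param session a [render_session()] result.
#' @param ttl a [generate_ttl_logs()] result for the same cameras.
#' @param dir output directory (created if needed).
#' @param write_frames write PNG frames (can be slow for long sessions).
#' @param max_frames cap on frames written per camera (NULL = all).
#' @return invisibly, `dir`.
#' @export
write_session <- function(session, ttl, dir, write_frames = TRUE,
                          max_frames = NULL) {
  stopifnot(inherits(session, "rendered_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ci in seq_along(session)) {
    cam_dir <- file.path(dir, sprintf("cam%d", ci))
    dir.create(cam_dir, showWarnings = FALSE)
    s <- session[[ci]]
    utils::write.csv(data.frame(frame_index = seq_along(s$timestamps$times),
                                device_time_s = s$timestamps$times),
                     file.path(cam_dir, "frametimes.csv"), row.names = FALSE)
    dev <- ttl$device[[ci]]
    utils::write.csv(data.frame(transition_index = dev$transition_index,
                                state = dev$state, device_time_s = dev$time_s),
                     file.path(cam_dir, "ttl.csv"), row.names = FALSE)
    if (write_frames) {
      n <- length(s$timestamps$times)
      if (!is.null(max_frames)) n <- min(n, max_frames)
      for (i in seq_len(n)) {
        png::writePNG(s$frame(i) / 255,
                      file.path(cam_dir, sprintf("frame_%06d.png", i)))
      }
    }
  }
  utils::write.csv(data.frame(transition_index = ttl$daq$transition_index,
                              state = ttl$daq$state, time_s = ttl$daq$time_s),
                   file.path(dir, "ttl_daq.csv"), row.names = FALSE)
  gt <- session[[1]]$truth
  utils::write.csv(data.frame(time_s = gt$acq_time_s, x_cm = gt$x_cm,
                              y_cm = gt$y_cm, hd_deg = gt$hd_deg),
                   file.path(dir, "groundtruth.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_cameras = length(session),
                        frame_rate_hz = session[[1]]$camera$frame_rate,
                        image_size_px = as.integer(session[[1]]$camera$image_size)),
                   file.path(dir, "scene.yaml"))
  invisible(dir)
}

#' Read per-camera timestamp and TTL files from a session directory
#'
#' @param dir session directory written by [write_session()].
#' @return list with per-camera `timestamps` ([frame_timestamp_series()]),
#'   `ttl_device` data.frames, `ttl_daq`, and `frame_files` (per camera,
#'   possibly empty).
#' @export
read_session_dir <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  cams <- sort(list.dirs(dir, recursive = FALSE))
  cams <- cams[grepl("cam[0-9]+$", cams)]
  if (length(cams) == 0) abort(sprintf("no camera directories found in %s", dir))
  ts <- list(); ttl <- list(); frames <- list()
  for (ci in seq_along(cams)) {
    ft <- utils::read.csv(file.path(cams[ci], "frametimes.csv"))
    ts[[ci]] <- frame_timestamp_series(ft$device_time_s, cfg$frame_rate_hz, ci)
    tt <- utils::read.csv(file.path(cams[ci], "ttl.csv"))
    ttl[[ci]] <- data.frame(transition_index = tt$transition_index,
                            state = tt$state, time_s = tt$device_time_s)
    frames[[ci]] <- sort(list.files(cams[ci], pattern = "^frame_.*\\.png$",
                                    full.names = TRUE))
  }
  daq <- utils::read.csv(file.path(dir, "ttl_daq.csv"))
  list(timestamps = ts, ttl_device = ttl, ttl_daq = daq,
       frame_files = frames, config = cfg)
}

#' Read a PNG frame as a 0..255 colour array
#' @param path PNG file path.
#' @return numeric array [rows, cols, 3].
#' @export
read_frame_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}
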