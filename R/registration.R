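# Multi-camera registration: feature matching between calibration frames,
# RANSAC homography estimation, chaining of pairwise homographies into one
# shared arena canvas, and projection-error quality control.

#' Detect blob features and descriptors in a grayscale calibration frame
#'
#' Features are bright saturated cores (connected components above
#' `threshold`); each is described by the surrounding mean-normalized
#' intensity patch, which is locally unique on the calibration pattern.
#'
#' @param frame grayscale matrix, 0..255.
#' @param threshold detection intensity threshold.
#' @param patch_radius descriptor patch radius, pixels.
#' @return list with `keypoints` (n x 2 pixel coords) and `descriptors`
#'   (n x d matrix, unit norm).
#' @export
detect_blob_features <- function(frame, threshold = 200, patch_radius = 6) {
  stopifnot(is.matrix(frame))
  lab <- label_components(frame >= threshold, connectivity = 8)
  k <- max(lab)
  if (k == 0) return(list(keypoints = matrix(0, 0, 2), descriptors = matrix(0, 0, 0)))
  idx <- which(lab > 0)
  rows <- ((idx - 1L) %% nrow(frame)) + 1L
  cols <- ((idx - 1L) %/% nrow(frame)) + 1L
  comp <- lab[idx]
  cx <- tapply(cols, comp, mean)
  cy <- tapply(rows, comp, mean)
  sizes <- tabulate(comp, k)
  keep <- sizes >= 3
  kp <- cbind(cx[keep], cy[keep])
  off <- expand.grid(dx = -patch_radius:patch_radius, dy = -patch_radius:patch_radius)
  desc <- matrix(0, nrow(kp), nrow(off))
  for (i in seq_len(nrow(kp))) {
    v <- bilinear_sample(frame, kp[i, 1] + off$dx, kp[i, 2] + off$dy, fill = 0)
    v <- v - mean(v)
    n <- sqrt(sum(v^2))
    desc[i, ] <- if (n > 0) v / n else v
  }
  list(keypoints = unname(kp), descriptors = desc)
}

#' Match features between two calibration frames
#'
#' Mutual nearest neighbours in descriptor space passing Lowe's ratio test,
#' ordered by match quality. Fewer than 4 matches flags the pair as
#' unregistrable.
#'
#' @param frame_a,frame_b grayscale matrices (0..255).
#' @param ratio ratio-test threshold (best / second-best descriptor distance).
#' @param threshold,patch_radius passed to [detect_blob_features()].
#' @return object of class `correspondence_set`: data.frame with `ax`, `ay`,
#'   `bx`, `by` (pixel coords) and `score` (descriptor distance, ascending),
#'   with attribute `registrable`.
#' @export
match_features <- function(frame_a, frame_b, ratio = 0.8,
                           threshold = 200, patch_radius = 6) {
  fa <- detect_blob_features(frame_a, threshold, patch_radius)
  fb <- detect_blob_features(frame_b, threshold, patch_radius)
  correspondences_from_features(fa, fb, ratio)
}

#' @noRd
correspondences_from_features <- function(fa, fb, ratio = 0.8) {
  na <- nrow(fa$keypoints); nb <- nrow(fb$keypoints)
  empty <- data.frame(ax = numeric(0), ay = numeric(0),
                      bx = numeric(0), by = numeric(0), score = numeric(0))
  if (na == 0 || nb == 0) return(as_correspondence_set(empty))
  # squared descriptor distances via the unit-norm inner product
  sim <- fa$descriptors %*% t(fb$descriptors)
  d2 <- pmax(2 - 2 * sim, 0)
  best_b <- max.col(-d2)
  rows <- list()
  for (i in seq_len(na)) {
    j <- best_b[i]
    di <- sqrt(d2[i, j])
    second <- if (nb > 1) sqrt(min(d2[i, -j])) else Inf
    mutual <- which.min(d2[, j]) == i
    if (mutual && (di < ratio * second)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ax = fa$keypoints[i, 1], ay = fa$keypoints[i, 2],
        bx = fb$keypoints[j, 1], by = fb$keypoints[j, 2], score = di)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  as_correspondence_set(out[order(out$score), , drop = FALSE])
}

#' Build a correspondence set from explicit point pairs
#'
#' @param a,b n x 2 matrices of corresponding pixel coordinates.
#' @param score optional match scores.
#' @return a `correspondence_set`.
#' @export
correspondence_set <- function(a, b, score = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(nrow(a) == nrow(b), ncol(a) == 2, ncol(b) == 2)
  as_correspondence_set(data.frame(ax = a[, 1], ay = a[, 2],
                                   bx = b[, 1], by = b[, 2],
                                   score = score %||% rep(0, nrow(a))))
}

#' @noRd
as_correspondence_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("correspondence_set", "data.frame")
  attr(df, "registrable") <- nrow(df) >= 4
  df
}

#' RANSAC homography estimation from correspondences
#'
#' Samples minimal 4-point hypotheses, scores them by the number of
#' correspondences whose reprojection error is below `inlier_threshold`, and
#' refits the winning homography by least squares (normalized DLT) on its
#' full consensus set. The returned homography maps frame-A pixels onto
#' frame-B pixels and is normalized so `H[3,3] = 1`.
#'
#' @param corr a `correspondence_set` (>= 4 rows).
#' @param inlier_threshold reprojection error threshold, pixels.
#' @param max_iter maximum number of hypotheses (adaptively terminated).
#' @param seed integer seed.
#' @return list with `H`, `inliers` (logical mask), `n_inliers`, `rmse`
#'   (inlier reprojection RMSE).
#' @export
estimate_homography_ransac <- function(corr, inlier_threshold = 2,
                                       max_iter = 1000, seed = 1) {
  if (nrow(corr) < 4) abort("RANSAC needs at least 4 correspondences")
  src <- cbind(corr$ax, corr$ay)
  dst <- cbind(corr$bx, corr$by)
  n <- nrow(src)
  with_local_seed(seed, {
    best_mask <- NULL
    best_count <- 0L
    iter_needed <- max_iter
    i <- 0L
    while (i < min(max_iter, iter_needed)) {
      i <- i + 1L
      pick <- sample.int(n, 4)
      H <- tryCatch(fit_homography(src[pick, ], dst[pick, ]),
                    error = function(e) NULL, warning = function(w) NULL)
      if (is.null(H) || !all(is.finite(H))) next
      err <- suppressWarnings(reprojection_error(H, src, dst))
      mask <- is.finite(err) & err < inlier_threshold
      cnt <- sum(mask)
      if (cnt > best_count) {
        best_count <- cnt
        best_mask <- mask
        # adaptive stopping: 99.9% chance of one all-inlier sample
        w <- cnt / n
        iter_needed <- if (w >= 1) i else
          ceiling(log(0.001) / log(max(1 - w^4, 1e-12)))
      }
    }
    if (is.null(best_mask) || best_count < 4)
      abort(sprintf("RANSAC failed: no hypothesis reached 4 inliers (best %d of %d correspondences)",
                    best_count, n))
    H <- fit_homography(src[best_mask, , drop = FALSE],
                        dst[best_mask, , drop = FALSE])
    err <- reprojection_error(H, src, dst)
    mask <- is.finite(err) & err < inlier_threshold
    if (sum(mask) >= 4) {
      H <- fit_homography(src[mask, , drop = FALSE], dst[mask, , drop = FALSE])
      err <- reprojection_error(H, src, dst)
      mask <- is.finite(err) & err < inlier_threshold
    } else mask <- best_mask
    list(H = H, inliers = mask, n_inliers = sum(mask),
         rmse = sqrt(mean(err[mask]^2)))
  })
}

#' Per-camera registration into the shared canvas
#'
#' @param camera camera id.
#' @param H 3x3 homography, image pixels -> canvas cm.
#' @param inliers supporting inlier count.
#' @param canvas_bounds c(xmin, xmax, ymin, ymax) cm.
#' @param cm_per_px canvas scale relative to the reference camera's pixels.
#' @return object of class `camera_registration`.
#' @export
camera_registration <- function(camera, H, inliers = NA_integer_,
                                canvas_bounds = NULL, cm_per_px = NA_real_) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  if (abs(det(H)) < 1e-12) abort("registration homography must be invertible")
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  structure(list(camera = camera, H = H, H_inv = solve(H),
                 inliers = inliers, canvas_bounds = canvas_bounds,
                 cm_per_px = cm_per_px),
            class = "camera_registration")
}

#' Warp a pixel point into canvas coordinates (or back)
#'
#' @param p point(s): length-2 vector or n x 2 matrix.
#' @param reg a [camera_registration()].
#' @param inverse map canvas cm -> image pixels instead.
#' @return n x 2 matrix of mapped points.
#' @export
warp_point <- function(p, reg, inverse = FALSE) {
  stopifnot(inherits(reg, "camera_registration"))
  apply_homography(if (inverse) reg$H_inv else reg$H, p)
}

#' Register all cameras into one canvas
#'
#' Matches calibration frames pairwise, estimates pairwise homographies with
#' RANSAC, chains them along a maximum-inlier spanning tree rooted at the
#' reference camera, and fixes the metric scale from a declared landmark
#' distance (or an explicit cm-per-pixel value). The reference camera's
#' ground plane defines the canvas axes; the canvas origin is shifted so all
#' warped image corners have nonnegative coordinates.
#'
#' @param frames list of grayscale calibration frames (0..255 matrices), or
#'   NULL when `pair_matches` supplies every needed pair.
#' @param ref_camera index of the reference camera.
#' @param cm_per_px metric scale of the reference camera's pixels; give this
#'   or `landmark`.
#' @param landmark list(camera, p1, p2, distance_cm): two pixel points in one
#'   camera a known distance apart.
#' @param ransac_px RANSAC inlier threshold, pixels.
#' @param seed integer seed.
#' @param min_matches minimum correspondences for a usable pair.
#' @param pair_matches optional named list `"i-j"` of `correspondence_set`s
#'   (frame i pixels -> frame j pixels), bypassing the detector.
#' @param image_sizes list/matrix of per-camera c(width, height); required
#'   when `frames` is NULL.
#' @return list of [camera_registration()], one per camera, with shared
#'   canvas bounds.
#' @export
build_canvas <- function(frames, ref_camera = 1, cm_per_px = NULL,
                         landmark = NULL, ransac_px = 2, seed = 1,
                         min_matches = 8, pair_matches = NULL,
                         image_sizes = NULL) {
  n_cam <- if (!is.null(frames)) length(frames) else length(image_sizes)
  if (n_cam < 1) abort("need at least one camera")
  if (is.null(image_sizes))
    image_sizes <- lapply(frames, function(f) c(ncol(f), nrow(f)))
  if (n_cam == 1) {
    H_ref <- list(diag(3))
    inl <- NA_integer_
  } else {
    # pairwise estimates on the overlap graph
    edges <- list()
    for (i in seq_len(n_cam - 1)) {
      for (j in (i + 1):n_cam) {
        key <- sprintf("%d-%d", i, j)
        corr <- if (!is.null(pair_matches) && !is.null(pair_matches[[key]])) {
          pair_matches[[key]]
        } else if (!is.null(frames)) {
          match_features(frames[[i]], frames[[j]])
        } else NULL
        if (is.null(corr) || nrow(corr) < max(4, min_matches)) next
        fit <- tryCatch(
          estimate_homography_ransac(corr, inlier_threshold = ransac_px,
                                     seed = seed + i * 131L + j),
          error = function(e) NULL)
        if (is.null(fit) || fit$n_inliers < max(4, min_matches)) next
        edges[[length(edges) + 1L]] <- list(i = i, j = j, H_ij = fit$H,
                                            inliers = fit$n_inliers)
      }
    }
    # spanning tree from the reference by best-edge-first traversal
    H_ref <- vector("list", n_cam)
    inl_v <- rep(NA_integer_, n_cam)
    H_ref[[ref_camera]] <- diag(3)
    repeat {
      progressed <- FALSE
      ord <- order(-vapply(edges, function(e) e$inliers, numeric(1)))
      for (e in edges[ord]) {
        if (!is.null(H_ref[[e$i]]) && is.null(H_ref[[e$j]])) {
          H_ref[[e$j]] <- H_ref[[e$i]] %*% solve(e$H_ij)
          inl_v[e$j] <- e$inliers
          progressed <- TRUE
        } else if (!is.null(H_ref[[e$j]]) && is.null(H_ref[[e$i]])) {
          H_ref[[e$i]] <- H_ref[[e$j]] %*% e$H_ij
          inl_v[e$i] <- e$inliers
          progressed <- TRUE
        }
      }
      if (!progressed) break
    }
    missing <- which(vapply(H_ref, is.null, logical(1)))
    if (length(missing))
      abort(sprintf("camera overlap graph is disconnected: camera(s) %s cannot be reached from reference %d",
                    paste(missing, collapse = ", "), ref_camera))
    inl <- inl_v
  }
  # metric scale
  if (is.null(cm_per_px)) {
    if (is.null(landmark)) abort("give either cm_per_px or a landmark distance")
    Hl <- H_ref[[landmark$camera]]
    p <- apply_homography(Hl, rbind(landmark$p1, landmark$p2))
    cm_per_px <- landmark$distance_cm / sqrt(sum((p[2, ] - p[1, ])^2))
  }
  # canvas bounds from all warped image corners, origin at the minimum corner
  corners <- do.call(rbind, lapply(seq_len(n_cam), function(ci) {
    w <- image_sizes[[ci]][1]; h <- image_sizes[[ci]][2]
    apply_homography(H_ref[[ci]], rbind(c(1, 1), c(w, 1), c(1, h), c(w, h)))
  }))
  corners_cm <- corners * cm_per_px
  t0 <- c(min(corners_cm[, 1]), min(corners_cm[, 2]))
  S <- similarity_transform(cm_per_px, -t0[1], -t0[2])
  bounds <- c(xmin = 0, xmax = max(corners_cm[, 1]) - t0[1],
              ymin = 0, ymax = max(corners_cm[, 2]) - t0[2])
  lapply(seq_len(n_cam), function(ci) {
    camera_registration(ci, S %*% H_ref[[ci]],
                        inliers = if (length(inl) > 1) inl[ci] else inl,
                        canvas_bounds = bounds, cm_per_px = cm_per_px)
  })
}

#' Projection-error report across cameras
#'
#' For every landmark (e.g. a string-grid intersection) observed by two or
#' more cameras, each camera's error is the distance (cm) between its
#' canvas-warped observation and the mean warped position over all observing
#' cameras.
#'
#' @param points data.frame with columns `intersection`, `camera` (index into
#'   `regs`), `px_x`, `px_y`.
#' @param regs list of [camera_registration()].
#' @return object of class `projection_error_report`: list with `errors`
#'   (data.frame intersection/camera/error_cm), `per_camera` (median and max
#'   per camera), `overall_median_cm`, `overall_max_cm`, `skipped`
#'   (intersections seen once).
#' @export
projection_error <- function(points, regs) {
  stopifnot(all(c("intersection", "camera", "px_x", "px_y") %in% names(points)))
  pts_cm <- matrix(NA_real_, nrow(points), 2)
  for (ci in unique(points$camera)) {
    sel <- points$camera == ci
    pts_cm[sel, ] <- warp_point(cbind(points$px_x[sel], points$px_y[sel]),
                                regs[[ci]])
  }
  errs <- list(); skipped <- c()
  for (id in unique(points$intersection)) {
    sel <- which(points$intersection == id)
    if (length(sel) < 2) { skipped <- c(skipped, id); next }
    ctr <- colMeans(pts_cm[sel, , drop = FALSE])
    e <- sqrt(rowSums(sweep(pts_cm[sel, , drop = FALSE], 2, ctr)^2))
    errs[[length(errs) + 1L]] <- data.frame(intersection = id,
                                            camera = points$camera[sel],
                                            error_cm = e)
  }
  if (!length(errs)) abort("no intersection observed by >= 2 cameras")
  errors <- do.call(rbind, errs)
  per_cam <- do.call(rbind, lapply(split(errors$error_cm, errors$camera),
                                   function(e) data.frame(median_cm = stats::median(e),
                                                          max_cm = max(e))))
  per_cam$camera <- as.integer(rownames(per_cam))
  structure(list(errors = errors,
                 per_camera = per_cam[, c("camera", "median_cm", "max_cm")],
                 overall_median_cm = stats::median(errors$error_cm),
                 overall_max_cm = max(errors$error_cm),
                 skipped = skipped),
            class = "projection_error_report")
}

#' @export
print.projection_error_report <- function(x, ...) {
  cat(sprintf("<projection_error_report> overall median %.3f cm, max %.3f cm (%d skipped)\n",
              x$overall_median_cm, x$overall_max_cm, length(x$skipped)))
  invisible(x)
}

#' Serialize registrations to JSON (and back)
#'
#' @param regs list of [camera_registration()].
#' @param path JSON file path.
#' @return `write_registrations`: invisibly `path`; `read_registrations`: the
#'   list of registrations.
#' @export
write_registrations <- function(regs, path) {
  payload <- lapply(regs, function(r) list(
    camera = r$camera,
    homography_row_major = as.numeric(t(r$H)),
    inliers = r$inliers,
    canvas_bounds = as.list(r$canvas_bounds),
    cm_per_px = r$cm_per_px))
  jsonlite::write_json(list(schema = "arenatrack.registration.v1",
                            cameras = payload),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_registrations
#' @export
read_registrations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj$cameras)), function(i) {
    row <- obj$cameras[i, ]
    camera_registration(row$camera,
                        matrix(unlist(row$homography_row_major), 3, 3, byrow = TRUE),
                        inliers = row$inliers,
                        canvas_bounds = unlist(row$canvas_bounds),
                        cm_per_px = row$cm_per_px)
  })
}
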