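# Planar homography primitives.
#
# Overhead cameras imaging a planar arena floor are related to arena (canvas)
# coordinates by 3x3 projective transforms. Points are row-wise (x, y)
# matrices; homographies act on homogeneous coordinates and are normalized so
# H[3,3] = 1 wherever that entry is nonzero.

#' Apply a homography to 2D points
#'
#' @param H 3x3 homography matrix.
#' @param pts n x 2 matrix (or length-2 vector) of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates. Points mapping to infinity
#'   (homogeneous w ~ 0) come back as `NaN` with a warning.
#' @export
apply_homography <- function(H, pts) {
  stopifnot(is.matrix(H), all(dim(H) == c(3, 3)))
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  stopifnot(ncol(pts) == 2)
  ph <- cbind(pts, 1) %*% t(H)
  w <- ph[, 3]
  bad <- abs(w) < 1e-12
  if (any(bad)) {
    warning("point(s) map to infinity under homography; returning NaN")
    w[bad] <- NA_real_
  }
  cbind(ph[, 1] / w, ph[, 2] / w)
}

#' Direct linear transform homography fit
#'
#' Least-squares estimate of the homography mapping `src` onto `dst` using the
#' normalized DLT (Hartley normalization: translate to centroid, scale to mean
#' distance sqrt(2)). Exact for 4 point pairs in general position.
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 4.
#' @return 3x3 homography with H[3,3] = 1.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n) abort("fit_homography needs >= 4 corresponding point pairs")
  Ts <- normalizing_transform(src)
  Td <- normalizing_transform(dst)
  s <- apply_homography(Ts, src)
  d <- apply_homography(Td, dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

#' @noRd
normalizing_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Reprojection error of correspondences under a homography
#' @noRd
reprojection_error <- function(H, src, dst) {
  proj <- apply_homography(H, src)
  sqrt(rowSums((proj - dst)^2))
}

#' Build a similarity transform (uniform scale + translation)
#' @noRd
similarity_transform <- function(scale = 1, tx = 0, ty = 0) {
  matrix(c(scale, 0, tx,
           0, scale, ty,
           0, 0, 1), 3, 3, byrow = TRUE)
}
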