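# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, seeded RNG state
#'
#' Runs `expr` with `set.seed(seed)` in effect and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the global stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap angles into [0, 360)
#' @noRd
wrap_deg <- function(x) {
  x <- x %% 360
  x[x == 360] <- 0
  x
}

#' Smallest signed angular difference a - b in degrees, in (-180, 180]
#' @noRd
ang_diff_deg <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

#' Label connected components of a logical matrix
#'
#' Flood-fill labelling used for LED pixel clusters and place-field
#' segmentation. Returns an integer matrix of the same shape with 0 for
#' background and labels 1..k for the components, ordered by discovery.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbours) or 8 (edge + diagonal).
#' @return integer matrix of component labels.
#' @keywords internal
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  todo <- which(mask)
  current <- 0L
  stack <- integer(length(todo))
  for (start in todo) {
    if (lab[start] != 0L) next
    current <- current + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- current
    while (top > 0L) {
      idx <- stack[top]; top <- top - 1L
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        idx2 <- r2 + (c2 - 1L) * nr
        if (mask[idx2] && lab[idx2] == 0L) {
          lab[idx2] <- current
          top <- top + 1L
          stack[top] <- idx2
        }
      }
    }
  }
  lab
}

#' Discrete Gaussian kernel (1D), normalized to sum 1
#' @noRd
gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Bilinear sample of a single-channel image matrix at (x, y) pixel coords
#'
#' Coordinates follow the package convention: x indexes columns, y indexes
#' rows, pixel centres at integers starting from 1. Points outside the image
#' return `fill`.
#' @noRd
bilinear_sample <- function(img, x, y, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= nc & y0 + 1 <= nr
  out <- rep(fill, length(x))
  if (any(ok)) {
    i00 <- cbind(y0[ok], x0[ok])
    i01 <- cbind(y0[ok], x0[ok] + 1)
    i10 <- cbind(y0[ok] + 1, x0[ok])
    i11 <- cbind(y0[ok] + 1, x0[ok] + 1)
    out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      img[i01] * fx[ok] * (1 - fy[ok]) +
      img[i10] * (1 - fx[ok]) * fy[ok] +
      img[i11] * fx[ok] * fy[ok]
  }
  out
}

#' @noRd
is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Stop with a call-free message
#' @noRd
abort <- function(...) stop(..., call. = FALSE)
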