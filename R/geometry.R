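# Projective-geometry primitives shared by the synthetic renderer and the
# rectification pipeline. Points are given in continuous pixel coordinates:
# x to the right, y down, origin at the centre of the top-left pixel.

#' Fit a homography from point correspondences
#'
#' Estimates the 3x3 projective matrix mapping `src` points onto `dst` points
#' by the direct linear transform. With exactly four correspondences the fit
#' is exact; with more it is least squares (smallest singular vector).
#'
#' @param src,dst numeric matrices with columns x, y and one row per point
#'   (at least four rows each).
#' @return a 3x3 matrix `H` such that `H %*% c(x, y, 1)` is proportional to
#'   the destination point.
#' @export
fit_homography <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 4L || nrow(src) != nrow(dst) || ncol(src) != 2L || ncol(dst) != 2L) {
    abort("`src` and `dst` must be n x 2 matrices with n >= 4.")
  }
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- src[i, 1L]; y <- src[i, 2L]
    u <- dst[i, 1L]; v <- dst[i, 2L]
    A[2L * i - 1L, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
    A[2L * i, ]      <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
  }
  if (n == 4L) {
    # exact solve with h33 fixed to 1 (non-degenerate quadrilaterals)
    h <- solve(A[, 1:8], -A[, 9L])
    H <- matrix(c(h, 1), 3L, 3L, byrow = TRUE)
  } else {
    e <- eigen(crossprod(A), symmetric = TRUE)
    h <- e$vectors[, 9L]  # null-space (smallest eigenvalue) direction
    H <- matrix(h, 3L, 3L, byrow = TRUE)
    if (abs(H[3L, 3L]) > 1e-12) H <- H / H[3L, 3L]
  }
  H
}

#' Apply a homography to points
#'
#' @param H 3x3 projective matrix.
#' @param xy n x 2 matrix of points (columns x, y).
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  p <- cbind(xy, 1) %*% t(H)
  cbind(p[, 1L] / p[, 3L], p[, 2L] / p[, 3L])
}

# TRUE when the quadrilateral (rows ordered around the boundary) is strictly
# convex: all cross products of consecutive edges share one sign.
quad_is_convex <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) != 4L) return(FALSE)
  z <- vapply(1:4, function(i) {
    a <- q[i %% 4L + 1L, ] - q[i, ]
    b <- q[(i + 1L) %% 4L + 1L, ] - q[i %% 4L + 1L, ]
    a[1L] * b[2L] - a[2L] * b[1L]
  }, numeric(1))
  all(z > 0) || all(z < 0)
}

# Bilinear sampling of a H x W x C array at continuous coordinates.
# Coordinates within 1e-6 of an integer are snapped so that an identity
# mapping reproduces the input bit for bit. Out-of-range samples return `fill`.
bilinear_sample <- function(img, x, y, fill = 0) {
  d <- dim(img)
  h <- d[1L]; w <- d[2L]; nc <- if (length(d) == 3L) d[3L] else 1L
  snap <- function(v) {
    r <- round(v)
    ifelse(abs(v - r) < 1e-6, r, v)
  }
  x <- snap(x); y <- snap(y)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  x1 <- x0 + 1;   y1 <- y0 + 1
  inside <- x0 >= -1 & x1 <= w & y0 >= -1 & y1 <= h - 0 &
    x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  cx0 <- pmin(pmax(x0, 0), w - 1); cx1 <- pmin(pmax(x1, 0), w - 1)
  cy0 <- pmin(pmax(y0, 0), h - 1); cy1 <- pmin(pmax(y1, 0), h - 1)
  out <- array(fill, dim = c(length(x), nc))
  for (ch in seq_len(nc)) {
    plane <- if (length(d) == 3L) img[, , ch] else img
    v00 <- plane[cbind(cy0 + 1L, cx0 + 1L)]
    v01 <- plane[cbind(cy0 + 1L, cx1 + 1L)]
    v10 <- plane[cbind(cy1 + 1L, cx0 + 1L)]
    v11 <- plane[cbind(cy1 + 1L, cx1 + 1L)]
    val <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
      v10 * (1 - fx) * fy + v11 * fx * fy
    val[!inside] <- fill
    out[, ch] <- val
  }
  out
}
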