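# Grid-line detection and perspective geometry: the tray's cell boundaries
# are linear features in the colour-filtered image; a Hough transform finds
# them, their intersections define the tray plane, and a homography fitted to
# the outer corners registers the photo to an orthographic view.

#' Detect tray grid lines with a Hough transform
#'
#' Votes mask pixels into a (rho, theta) accumulator (rho resolution 1 px,
#' theta resolution 0.25 degrees, orientation classes within +/-20 degrees of
#' vertical and horizontal), picks the top `expected_per_axis` peaks per class
#' after non-maximum suppression (radius: half the expected line spacing,
#' ties broken towards smaller rho), and refines each peak by a total
#' least-squares fit to the mask pixels within a 2 px band of the line
#' (pixels near a crossing line of the other orientation are excluded so
#' junctions do not bias the fit).
#'
#' @param mask logical H x W matrix of candidate line pixels (the ridge
#'   pixels of the colour-filtered tray image).
#' @param expected_per_axis number of lines per orientation class
#'   (rows + 1 horizontal, cols + 1 vertical). Either a single count used for
#'   both axes or `c(horizontal, vertical)`.
#' @param theta_window half-width (degrees) of each orientation class.
#' @param theta_res,rho_res accumulator resolution (degrees, pixels).
#' @param min_votes minimum accumulator votes for a peak; defaults to a
#'   quarter of the smaller mask dimension.
#' @param refine_band half-width (px) of the refinement band.
#' @return tibble with columns `orientation` ("horizontal"/"vertical"),
#'   `rho` (px), `theta` (radians in `[0, pi)`), `votes`, `position` (the
#'   line's coordinate where it crosses the central axis; sort key), such
#'   that pixels on the line satisfy `x cos(theta) + y sin(theta) = rho`.
#' @export
detect_grid_lines <- function(mask, expected_per_axis,
                              theta_window = 20, theta_res = 0.25,
                              rho_res = 1, min_votes = NULL,
                              refine_band = 2) {
  if (!any(mask)) abort("Empty mask: no line pixels to vote with.")
  if (length(expected_per_axis) == 1L) {
    expected_per_axis <- rep(expected_per_axis, 2L)
  }
  h <- nrow(mask); w <- ncol(mask)
  min_votes <- min_votes %||% 0.25 * min(h, w)
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
  diag_len <- ceiling(sqrt(h^2 + w^2))
  rho_off <- diag_len + 1L
  n_rho <- 2L * diag_len + 1L
  deg <- pi / 180
  classes <- list(
    vertical = seq(-theta_window, theta_window, by = theta_res) * deg,
    horizontal = seq(90 - theta_window, 90 + theta_window, by = theta_res) * deg)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2

  peaks <- list()
  for (cl in names(classes)) {
    thetas <- classes[[cl]]
    acc <- matrix(0L, n_rho, length(thetas))
    for (j in seq_along(thetas)) {
      rho <- round((x * cos(thetas[j]) + y * sin(thetas[j])) / rho_res)
      acc[, j] <- tabulate(rho + rho_off, nbins = n_rho)
    }
    n_want <- expected_per_axis[if (cl == "horizontal") 1L else 2L]
    spacing <- (if (cl == "horizontal") h else w) / max(1L, n_want - 1L)
    nms <- spacing / 2
    found <- list()
    for (k in seq_len(n_want)) {
      m <- max(acc)
      if (m < min_votes) {
        abort(sprintf("Axis '%s': found only %d line(s) above threshold, expected %d.",
                      cl, k - 1L, n_want))
      }
      hit <- which(acc == m, arr.ind = TRUE)
      hit <- unname(hit[order(hit[, 1L]), , drop = FALSE][1L, ])  # tie-break: smaller rho
      th <- thetas[hit[2L]]
      rh <- (hit[1L] - rho_off) * rho_res
      found[[k]] <- c(rho = rh, theta = th, votes = m)
      # suppress every accumulator line passing near this line's central point
      tpar <- rh - cx * cos(th) - cy * sin(th)
      px <- cx + tpar * cos(th); py <- cy + tpar * sin(th)
      for (j in seq_along(thetas)) {
        r0 <- px * cos(thetas[j]) + py * sin(thetas[j])
        lo <- max(1L, floor((r0 - nms) / rho_res) + rho_off)
        hi <- min(n_rho, ceiling((r0 + nms) / rho_res) + rho_off)
        if (lo <= hi) acc[lo:hi, j] <- 0L
      }
    }
    peaks[[cl]] <- dplyr::bind_rows(lapply(found, as.list)) |>
      dplyr::mutate(orientation = cl)
  }
  lines <- dplyr::bind_rows(peaks)

  # total-least-squares refinement, junction pixels excluded
  ref <- purrr::pmap(lines, function(rho, theta, votes, orientation) {
    d_self <- abs(x * cos(theta) + y * sin(theta) - rho)
    other <- lines[lines$orientation != orientation, , drop = FALSE]
    near_other <- rep(FALSE, length(x))
    for (i in seq_len(nrow(other))) {
      near_other <- near_other |
        (abs(x * cos(other$theta[i]) + y * sin(other$theta[i]) - other$rho[i]) <
           refine_band + 1)
    }
    sel <- d_self <= refine_band & !near_other
    if (sum(sel) < 2L) sel <- d_self <= refine_band
    xs <- x[sel]; ys <- y[sel]
    mx <- mean(xs); my <- mean(ys)
    cv <- cbind(c(sum((xs - mx)^2), sum((xs - mx) * (ys - my))),
                c(sum((xs - mx) * (ys - my)), sum((ys - my)^2)))
    ev <- eigen(cv, symmetric = TRUE)
    nrm <- ev$vectors[, 2L]  # minor axis = line normal
    th <- atan2(nrm[2L], nrm[1L])
    rh <- mx * nrm[1L] + my * nrm[2L]
    if (th < 0) { th <- th + pi; rh <- -rh }
    if (th >= pi) { th <- th - pi; rh <- -rh }
    list(rho = rh, theta = th, votes = votes, orientation = orientation)
  })
  lines <- dplyr::bind_rows(ref)
  # sort key: coordinate where the line crosses the central image axis
  lines$position <- ifelse(
    lines$orientation == "vertical",
    (lines$rho - cy * sin(lines$theta)) / cos(lines$theta),
    (lines$rho - cx * cos(lines$theta)) / sin(lines$theta))
  lines |>
    dplyr::arrange(.data$orientation, .data$position) |>
    dplyr::select("orientation", "rho", "theta", "votes", "position") |>
    as_tibble()
}

#' Build the grid model from detected lines
#'
#' Intersects every horizontal with every vertical line to obtain the
#' (rows+1) x (cols+1) corner mesh, and fits the homography mapping the four
#' outer corners onto an axis-aligned square grid of side `cell_px` per cell.
#' Interior corners are used only to report fit residuals.
#'
#' @param lines tibble from [detect_grid_lines()].
#' @param image_shape `c(height, width)` of the image the lines live in.
#' @param cell_px rectified cell side (px); default: the median spacing of
#'   the detected lines, rounded.
#' @return a `chill_grid`: corner array `[n_h, n_v, 2]` (x, y), `homography`
#'   (image -> orthographic), `inv_homography`, `rows`, `cols`, `cell_px`,
#'   and `residual_px` (RMS of interior corners against the ideal grid).
#' @export
compute_grid <- function(lines, image_shape, cell_px = NULL) {
  hl <- lines[lines$orientation == "horizontal", , drop = FALSE]
  vl <- lines[lines$orientation == "vertical", , drop = FALSE]
  nh <- nrow(hl); nv <- nrow(vl)
  if (nh < 2L || nv < 2L) abort("Need at least two lines per orientation.")
  h <- image_shape[1L]; w <- image_shape[2L]
  # duplicate / intersecting same-class lines -> degenerate grid
  for (cls in list(hl, vl)) {
    n <- nrow(cls)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      A <- rbind(c(cos(cls$theta[i]), sin(cls$theta[i])),
                 c(cos(cls$theta[j]), sin(cls$theta[j])))
      if (abs(det(A)) < 1e-12) {
        if (abs(cls$rho[i] - cls$rho[j]) < 1) {
          abort("Degenerate grid: two coincident lines in one orientation class.")
        }
        next
      }
      p <- solve(A, c(cls$rho[i], cls$rho[j]))
      if (p[1L] >= -1 && p[1L] <= w && p[2L] >= -1 && p[2L] <= h) {
        abort("Degenerate grid: same-orientation lines intersect inside the image.")
      }
    }
  }
  corners <- array(NA_real_, dim = c(nh, nv, 2L))
  for (i in seq_len(nh)) for (j in seq_len(nv)) {
    A <- rbind(c(cos(vl$theta[j]), sin(vl$theta[j])),
               c(cos(hl$theta[i]), sin(hl$theta[i])))
    if (abs(det(A)) < 1e-12) abort("Degenerate grid: horizontal and vertical lines are parallel.")
    p <- solve(A, c(vl$rho[j], hl$rho[i]))
    corners[i, j, ] <- p
  }
  # mesh must be monotone in both indices
  cx_mat <- corners[, , 1L]; cy_mat <- corners[, , 2L]
  if (any(t(apply(cx_mat, 1L, diff)) <= 0) || any(apply(cy_mat, 2L, diff) <= 0)) {
    abort("Corner mesh is not monotone; grid detection failed.")
  }
  if (is.null(cell_px)) {
    sp <- c(diff(vl$position), diff(hl$position))
    cell_px <- max(1L, round(median(sp)))
  }
  cell_px <- as.integer(cell_px)
  Wg <- (nv - 1L) * cell_px; Hg <- (nh - 1L) * cell_px
  src <- rbind(corners[1L, 1L, ], corners[1L, nv, ],
               corners[nh, nv, ], corners[nh, 1L, ])
  dst <- rbind(c(-0.5, -0.5), c(Wg - 0.5, -0.5),
               c(Wg - 0.5, Hg - 0.5), c(-0.5, Hg - 0.5))
  H_img2ortho <- fit_homography(src, dst)
  if (abs(det(H_img2ortho)) < 1e-10) abort("Non-invertible homography.")
  H_ortho2img <- solve(H_img2ortho)
  # residuals of interior corners against the ideal lattice
  ij <- expand.grid(i = seq_len(nh), j = seq_len(nv))
  obs <- cbind(corners[, , 1L][as.matrix(ij[, 1:2])],
               corners[, , 2L][as.matrix(ij[, 1:2])])
  mapped <- apply_homography(H_img2ortho, obs)
  ideal <- cbind((ij$j - 1L) * cell_px - 0.5, (ij$i - 1L) * cell_px - 0.5)
  resid <- sqrt(mean(rowSums((mapped - ideal)^2)))
  structure(list(corners = corners, homography = H_img2ortho,
                 inv_homography = H_ortho2img,
                 rows = nh - 1L, cols = nv - 1L, cell_px = cell_px,
                 residual_px = resid),
            class = "chill_grid")
}

#' Rectify an image to the orthographic tray plane
#'
#' Applies the grid homography to the original (unfiltered) image by inverse
#' mapping with bilinear interpolation. The output is
#' `rows * cell_px` x `cols * cell_px`; an identity homography reproduces the
#' input pixels exactly.
#'
#' @param image numeric H x W x 3 array (0-255).
#' @param grid a `chill_grid` from [compute_grid()].
#' @return rectified numeric array.
#' @export
rectify <- function(image, grid) {
  if (!inherits(grid, "chill_grid")) abort("`grid` must be a `chill_grid`.")
  if (abs(det(grid$homography)) < 1e-10) abort("Non-invertible homography.")
  Hg <- grid$rows * grid$cell_px; Wg <- grid$cols * grid$cell_px
  xo <- rep(0:(Wg - 1L), each = Hg)
  yo <- rep(0:(Hg - 1L), times = Wg)
  src <- apply_homography(grid$inv_homography, cbind(xo, yo))
  vals <- bilinear_sample(image, src[, 1L], src[, 2L], fill = 0)
  out <- array(0, dim = c(Hg, Wg, 3L))
  for (ch in 1:3) out[, , ch] <- matrix(vals[, ch], Hg, Wg)
  out
}
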