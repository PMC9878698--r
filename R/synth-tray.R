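# Synthetic half-tray renderer. Emulates one camera frame of a Plug Tray-288
# half: a 12 x 12 well grid photographed from above, optionally under a
# projective (perspective) distortion, with exact per-cell ground truth for
# how many pixels pass the rosette colour filter in the unwarped frame.

#' Specify a synthetic tray
#'
#' @param rows,cols grid shape (>= 2 each); the default 12 x 12 matches one
#'   half of a 288-well plug tray.
#' @param cell_px pixels per cell side (>= 8).
#' @param tray_color,background_color,line_color RGB triples (0-255) for the
#'   tray surface, the bench background and the cell ridges.
#' @param warp optional 4 x 2 matrix of corner displacements (pixels) for the
#'   image corners in order top-left, top-right, bottom-right, bottom-left.
#'   Displacements are capped at 10 percent of the image size and must keep
#'   the warped quadrilateral convex.
#' @param noise_sd additive Gaussian intensity noise per channel (0-255
#'   scale), clipped to the valid range. Default 0: the generator pins down
#'   geometry, not sensor noise.
#' @param seed integer seed; all randomness in rendering flows from it.
#' @param apron_px tray-coloured margin around the well grid.
#' @param border_px background margin around the tray.
#' @return a `tray_spec` object.
#' @export
tray_spec <- function(rows = 12, cols = 12, cell_px = 80,
                      tray_color = c(180, 140, 90),
                      background_color = c(40, 40, 40),
                      line_color = c(90, 60, 30),
                      warp = NULL, noise_sd = 0, seed = 1L,
                      apron_px = 8, border_px = 24) {
  if (rows < 2 || cols < 2) abort("`rows` and `cols` must both be >= 2.")
  if (cell_px < 8) abort("`cell_px` must be >= 8.")
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  if (!is.null(warp)) {
    warp <- matrix(as.numeric(warp), 4L, 2L)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 cell_px = as.integer(cell_px),
                 tray_color = tray_color, background_color = background_color,
                 line_color = line_color, warp = warp,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 apron_px = as.integer(apron_px),
                 border_px = as.integer(border_px)),
            class = "tray_spec")
}

#' A rosette blob: a union of disks inside one cell
#'
#' Rosettes are modelled as unions of 3-9 overlapping disks (leaf lobes) in
#' cell-local continuous coordinates; the union pixel count is the ground
#' truth the imaging pipeline is judged against.
#'
#' @param cell_row,cell_col 0-based grid indices.
#' @param centers k x 2 matrix of disk centres in cell-local pixels
#'   (0 to cell_px).
#' @param radii length-k disk radii (pixels).
#' @param color RGB triple of the rosette (defaults to leaf green).
#' @export
rosette_blob <- function(cell_row, cell_col, centers, radii,
                         color = c(60, 140, 50)) {
  centers <- matrix(as.numeric(centers), ncol = 2L)
  if (nrow(centers) != length(radii)) abort("One radius per disk centre is required.")
  if (any(radii <= 0)) abort("Disk radii must be positive.")
  structure(list(cell_row = as.integer(cell_row), cell_col = as.integer(cell_col),
                 centers = centers, radii = as.numeric(radii), color = color),
            class = "rosette_blob")
}

#' Draw random rosettes spanning a range of target areas
#'
#' One rosette per requested cell; target areas are log-uniform across
#' `area_range` and realised as a central disk plus 2-8 satellite lobes,
#' all kept `margin` pixels clear of the cell boundary so no blob bleeds
#' across cells or touches a ridge.
#'
#' @param spec a [tray_spec()].
#' @param cells data frame with 0-based `cell_row`, `cell_col`; default all.
#' @param area_range target blob areas (pixels), log-uniform.
#' @param areas optional vector of per-cell target areas (overrides
#'   `area_range`), one per row of `cells`.
#' @param seed integer seed.
#' @param margin clearance from the cell boundary (pixels).
#' @return list of [rosette_blob()] objects.
#' @export
random_rosettes <- function(spec, cells = NULL, area_range = c(50, 4000),
                            areas = NULL, seed = spec$seed, margin = 4) {
  if (is.null(cells)) {
    cells <- expand.grid(cell_row = seq_len(spec$rows) - 1L,
                         cell_col = seq_len(spec$cols) - 1L)
  }
  cp <- spec$cell_px
  usable <- cp - 2 * margin
  if (usable < 4) abort("`cell_px` too small for the requested margin.")
  if (!is.null(areas) && length(areas) != nrow(cells)) {
    abort("`areas` must supply one target per cell.")
  }
  cells$.target_area <- if (is.null(areas)) NA_real_ else as.numeric(areas)
  withr::with_seed(seed, {
    purrr::pmap(cells, function(cell_row, cell_col, .target_area) {
      area <- if (is.na(.target_area)) {
        exp(runif(1, log(area_range[1L]), log(area_range[2L])))
      } else .target_area
      # central disk carries ~60% of the target area; lobes add the rest
      r0 <- sqrt(0.6 * area / pi)
      r0 <- min(r0, usable / 2 - 0.5)
      n_lobe <- sample(2:8, 1L)
      ang <- runif(n_lobe, 0, 2 * pi)
      rl <- pmax(1, sqrt(0.4 * area / pi) * runif(n_lobe, 0.3, 0.7))
      dist <- r0 * runif(n_lobe, 0.5, 0.9)
      cx <- cp / 2; cy <- cp / 2
      centers <- rbind(c(cx, cy),
                       cbind(cx + dist * cos(ang), cy + dist * sin(ang)))
      radii <- c(r0, rl)
      # clamp every disk inside the margin box
      lim_lo <- margin + radii + 0.5
      lim_hi <- cp - margin - radii - 0.5
      bad <- lim_lo > lim_hi
      radii[bad] <- pmax(1, (cp - 2 * margin) / 2 - 1)
      lim_lo <- margin + radii + 0.5
      lim_hi <- cp - margin - radii - 0.5
      centers[, 1L] <- pmin(pmax(centers[, 1L], lim_lo), lim_hi)
      centers[, 2L] <- pmin(pmax(centers[, 2L], lim_lo), lim_hi)
      rosette_blob(cell_row, cell_col, centers, radii)
    })
  })
}

# paint a colour into an image over a logical mask
paint <- function(img, mask, color) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Render a synthetic tray image with exact ground truth
#'
#' Renders the tray in an unwarped (orthographic) frame, measures the ground
#' truth there — for each cell, the exact count of pixels passing
#' `plant_filter` — and then optionally warps the frame by the tray's corner
#' homography (nearest-neighbour resampling, so colours stay exact).
#'
#' @param spec a [tray_spec()].
#' @param rosettes list of [rosette_blob()]s, each fully inside its cell.
#' @param plant_filter filter defining "plant" pixels for the manifest;
#'   default [default_plant_filter()].
#' @return a `chill_tray` list: `image` (H x W x 3, possibly warped),
#'   `manifest` (tibble: cell_row, cell_col, pixel_count, color_r/g/b),
#'   `spec`, and `warp_matrix` (3x3 homography, unwarped -> warped frame,
#'   or NULL).
#' @export
render_tray <- function(spec, rosettes = list(),
                        plant_filter = default_plant_filter()) {
  rows <- spec$rows; cols <- spec$cols; cp <- spec$cell_px
  gx0 <- spec$border_px + spec$apron_px
  gy0 <- gx0
  W <- 2L * (spec$border_px + spec$apron_px) + cols * cp
  H <- 2L * (spec$border_px + spec$apron_px) + rows * cp
  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- spec$background_color[ch]
  tr <- (spec$border_px + 1L):(H - spec$border_px)
  tc <- (spec$border_px + 1L):(W - spec$border_px)
  for (ch in 1:3) img[tr, tc, ch] <- spec$tray_color[ch]
  # ridges: 2 px wide, centred on each continuous cell boundary
  ridge_rows <- gy0:(gy0 + rows * cp + 1L)  # 1-based rows gy0-1..gy0+rows*cp (0-based)
  ridge_cols <- gx0:(gx0 + cols * cp + 1L)
  for (k in 0:cols) {
    cc <- gx0 + k * cp + c(0L, 1L)  # 1-based columns for 0-based gx0+k*cp-1, gx0+k*cp
    for (ch in 1:3) img[ridge_rows, cc, ch] <- spec$line_color[ch]
  }
  for (k in 0:rows) {
    rr <- gy0 + k * cp + c(0L, 1L)
    for (ch in 1:3) img[rr, ridge_cols, ch] <- spec$line_color[ch]
  }
  # blobs
  for (b in rosettes) {
    if (!inherits(b, "rosette_blob")) abort("`rosettes` must be rosette_blob objects.")
    if (b$cell_row < 0 || b$cell_row >= rows || b$cell_col < 0 || b$cell_col >= cols) {
      abort("Rosette outside the grid bounds.")
    }
    # cell-local pixel grid: local coordinate u for global 0-based column
    # X = gx0 + cell_col*cp + u, u in 0..cp-1
    u <- rep(0:(cp - 1L), times = cp)
    v <- rep(0:(cp - 1L), each = cp)
    inside <- rep(FALSE, cp * cp)
    for (d in seq_along(b$radii)) {
      inside <- inside |
        ((u - b$centers[d, 1L])^2 + (v - b$centers[d, 2L])^2 <= b$radii[d]^2)
    }
    if (!any(inside)) next
    # containment check: disks must stay >= 2 px off the cell boundary so the
    # blob cannot bleed into a neighbouring cell or onto a ridge
    if (any(u[inside] < 2) || any(u[inside] > cp - 3L) ||
        any(v[inside] < 2) || any(v[inside] > cp - 3L)) {
      abort(sprintf("Rosette in cell (%d,%d) bleeds over its cell boundary.",
                    b$cell_row, b$cell_col))
    }
    gr <- gy0 + b$cell_row * cp + v[inside] + 1L  # 1-based rows
    gc <- gx0 + b$cell_col * cp + u[inside] + 1L
    for (ch in 1:3) img[cbind(gr, gc, ch)] <- b$color[ch]
  }
  # sensor noise in the unwarped frame (ground truth is measured on it)
  if (spec$noise_sd > 0) {
    img <- withr::with_seed(spec$seed, {
      pmin(pmax(img + array(rnorm(length(img), 0, spec$noise_sd), dim = dim(img)),
                0), 255)
    })
  }
  # ground truth: plant-filter mask of the unwarped frame, counted per cell
  mask <- filter_color(img, plant_filter)
  idx <- which(mask, arr.ind = TRUE)
  x0 <- idx[, 2L] - 1L - gx0 + 1L  # 0-based x minus gx0  (off-by-one folded)
  y0 <- idx[, 1L] - 1L - gy0 + 1L
  cellc <- floor((x0 - 1L) / cp)
  cellr <- floor((y0 - 1L) / cp)
  grid <- expand.grid(cell_row = 0:(rows - 1L), cell_col = 0:(cols - 1L))
  key <- paste(cellr, cellc)
  counts <- table(factor(key, levels = paste(grid$cell_row, grid$cell_col)))
  manifest <- tibble(cell_row = grid$cell_row, cell_col = grid$cell_col,
                     pixel_count = as.integer(counts))
  blob_col <- tibble(
    cell_row = purrr::map_int(rosettes, "cell_row"),
    cell_col = purrr::map_int(rosettes, "cell_col"),
    color_r = purrr::map_dbl(rosettes, ~ .x$color[1L]),
    color_g = purrr::map_dbl(rosettes, ~ .x$color[2L]),
    color_b = purrr::map_dbl(rosettes, ~ .x$color[3L]))
  if (nrow(blob_col)) {
    blob_col <- dplyr::distinct(blob_col, .data$cell_row, .data$cell_col,
                                .keep_all = TRUE)
    manifest <- dplyr::left_join(manifest, blob_col,
                                 by = c("cell_row", "cell_col"))
  } else {
    manifest$color_r <- NA_real_; manifest$color_g <- NA_real_
    manifest$color_b <- NA_real_
  }
  manifest <- dplyr::arrange(manifest, .data$cell_row, .data$cell_col)

  warp_matrix <- NULL
  if (!is.null(spec$warp)) {
    lim <- 0.10 * max(W, H)
    if (any(abs(spec$warp) > lim)) {
      abort("Corner displacements exceed 10 percent of the image size.")
    }
    corners <- rbind(c(0, 0), c(W - 1, 0), c(W - 1, H - 1), c(0, H - 1))
    dst <- corners + spec$warp
    if (!quad_is_convex(dst)) abort("Warped tray quadrilateral is not convex.")
    warp_matrix <- fit_homography(corners, dst)
    Hinv <- solve(warp_matrix)
    xo <- rep(0:(W - 1L), each = H)
    yo <- rep(0:(H - 1L), times = W)
    src <- apply_homography(Hinv, cbind(xo, yo))
    sx <- round(src[, 1L]); sy <- round(src[, 2L])
    ok <- sx >= 0 & sx <= W - 1L & sy >= 0 & sy <= H - 1L
    warped <- array(0, dim = dim(img))
    for (ch in 1:3) {
      plane <- img[, , ch]
      out <- rep(spec$background_color[ch], W * H)
      out[ok] <- plane[cbind(sy[ok] + 1L, sx[ok] + 1L)]
      warped[, , ch] <- matrix(out, H, W)  # filled column-major: y fastest
    }
    img <- warped
  }
  structure(list(image = img, manifest = manifest, spec = spec,
                 warp_matrix = warp_matrix),
            class = "chill_tray")
}

#' Write a rendered tray to disk (PNG image + JSON manifest)
#'
#' @param tray a `chill_tray` from [render_tray()].
#' @param dir output directory (created if missing).
#' @param name file stem.
#' @return invisibly, the two paths written.
#' @export
write_tray <- function(tray, dir, name = "tray") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".png"))
  man_path <- file.path(dir, paste0(name, "_manifest.json"))
  png::writePNG(tray$image / 255, img_path)
  jsonlite::write_json(
    list(cells = tray$manifest,
         warp = if (is.null(tray$warp_matrix)) NULL else
           as.data.frame(tray$warp_matrix),
         seed = tray$spec$seed),
    man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(image = img_path, manifest = man_path))
}

#' Read a tray image from PNG into the package's raster convention
#' @param path PNG file.
#' @return numeric H x W x 3 array, 0-255.
#' @export
read_tray_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) abort("Grayscale PNG: a 3-channel RGB image is required.")
  img[, , 1:3, drop = FALSE] * 255
}
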