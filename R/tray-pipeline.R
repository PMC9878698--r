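# The six-step tray workflow: crop -> filter -> Hough lines -> grid ->
# rectify -> segment -> measure, composed in process_tray().

#' Crop the tray from a full camera frame
#'
#' Finds the largest tray-coloured region (after a morphological closing that
#' bridges the cell ridges), checks it covers at least `min_frac` of the
#' frame, and returns the tightest axis-aligned crop around it together with
#' the filled region mask. When no usable tray region is found the function
#' does not silently pass the full frame through: it returns `ok = FALSE`,
#' signalling that a manual crop (supplied via the pipeline config) is
#' required.
#'
#' @param image numeric H x W x 3 array (0-255).
#' @param tray_filter a [color_filter()] tuned to the tray surface.
#' @param min_frac minimum fraction of the frame the tray must occupy.
#' @param closing_px radius of the closing used to bridge ridges.
#' @return list: `ok`, and when `ok` is `TRUE` also `image` (cropped),
#'   `bbox` (0-based `c(x0, y0, x1, y1)`, inclusive), `quad` (4 x 2 corner
#'   matrix of the bounding quadrilateral) and `region` (filled tray mask in
#'   crop coordinates); when `FALSE`, a `reason` string.
#' @export
crop_tray <- function(image, tray_filter = default_tray_filter(),
                      min_frac = 0.2, closing_px = 3) {
  mask <- filter_color(image, tray_filter)
  if (!any(mask)) {
    return(list(ok = FALSE, reason = "no tray-coloured region found; manual crop required"))
  }
  brush <- EBImage::makeBrush(2L * closing_px + 1L, "disc")
  closed <- EBImage::closing(mask * 1, brush) > 0.5
  lab <- as.matrix(EBImage::bwlabel(closed * 1))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_frac * length(mask)) {
    return(list(ok = FALSE,
                reason = sprintf("largest tray-coloured region covers %.1f%% of the frame (< %.0f%%); manual crop required",
                                 100 * sizes[big] / length(mask), 100 * min_frac)))
  }
  comp <- lab == big
  region <- as.matrix(EBImage::fillHull(comp * 1)) > 0.5
  tray_px <- which(mask & comp, arr.ind = TRUE)
  y0 <- min(tray_px[, 1L]) - 1L; y1 <- max(tray_px[, 1L]) - 1L
  x0 <- min(tray_px[, 2L]) - 1L; x1 <- max(tray_px[, 2L]) - 1L
  list(ok = TRUE,
       image = image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), , drop = FALSE],
       bbox = c(x0 = x0, y0 = y0, x1 = x1, y1 = y1),
       quad = rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
       region = region[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L)])
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged with a small union-find pass.
label_components8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]   # down-right diagonal
  a2 <- lab[-1, -w]; b2 <- lab[-h, -1]   # up-right diagonal
  pair <- rbind(cbind(as.vector(a1), as.vector(b1)),
                cbind(as.vector(a2), as.vector(b2)))
  pair <- pair[pair[, 1L] > 0 & pair[, 2L] > 0 & pair[, 1L] != pair[, 2L], ,
               drop = FALSE]
  if (nrow(pair)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pair))) {
      ra <- find(pair[r, 1L]); rb <- find(pair[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    lab[lab > 0] <- match(root, sort(unique(root)))[lab[lab > 0]]
  }
  lab
}

#' Segment a rectified image into per-cell sub-images
#'
#' @param image rectified numeric array from [rectify()].
#' @param rows,cols grid shape.
#' @param cell_px cell side (px); default inferred from the image size.
#' @param margin optional inner margin (px) shaved off every cell edge to
#'   drop the ridge pixels.
#' @return tibble with 0-based `cell_row`, `cell_col` (row-major) and a
#'   list-column `image` of cell rasters.
#' @export
segment_cells <- function(image, rows, cols, cell_px = NULL, margin = 0) {
  d <- dim(image)
  cell_px <- cell_px %||% (d[1L] %/% rows)
  grid <- expand.grid(cell_col = 0:(cols - 1L), cell_row = 0:(rows - 1L))
  cells <- purrr::pmap(grid, function(cell_col, cell_row) {
    r0 <- cell_row * cell_px + 1L + margin
    r1 <- (cell_row + 1L) * cell_px - margin
    c0 <- cell_col * cell_px + 1L + margin
    c1 <- (cell_col + 1L) * cell_px - margin
    image[r0:r1, c0:c1, , drop = FALSE]
  })
  tibble(cell_row = grid$cell_row, cell_col = grid$cell_col, image = cells)
}

#' Measure the rosette in one cell image
#'
#' Applies the plant colour filter, labels 8-connected components, drops
#' components smaller than `min_blob_px`, and sums the area over ALL retained
#' components (a cell may hold a group of up to ~15 seedlings).
#'
#' @param cell numeric h x w x 3 cell raster.
#' @param plant_filter a [color_filter()] for healthy rosette leaves.
#' @param min_blob_px despeckle threshold: minimum component size (px).
#' @param calibration optional mm^2-per-pixel factor.
#' @return one-row tibble: `area_px`, `area_mm2` (NA without calibration),
#'   `mean_r`, `mean_g`, `mean_b` (NA when area is 0), `n_components`.
#' @export
measure_rosette <- function(cell, plant_filter = default_plant_filter(),
                            min_blob_px = 10, calibration = NULL) {
  mask <- filter_color(cell, plant_filter)
  lab <- label_components8(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_blob_px)
  sel <- lab %in% keep & lab > 0
  area <- sum(sel)
  if (area > 0) {
    mr <- mean(cell[, , 1L][sel]); mg <- mean(cell[, , 2L][sel])
    mb <- mean(cell[, , 3L][sel])
  } else {
    mr <- mg <- mb <- NA_real_
  }
  tibble(area_px = as.integer(area),
         area_mm2 = if (is.null(calibration)) NA_real_ else area * calibration,
         mean_r = mr, mean_g = mg, mean_b = mb,
         n_components = length(keep))
}

#' Pipeline configuration
#'
#' @param rows,cols grid shape of the tray (12 x 12 by default).
#' @param tray_filter,plant_filter colour filters for the tray surface and
#'   the rosettes.
#' @param cell_px rectified cell side; `NULL` infers it from the detected
#'   line spacing. Supply the known well size when comparing areas across
#'   images.
#' @param min_blob_px despeckle threshold for [measure_rosette()].
#' @param margin inner cell margin for segmentation.
#' @param calibration optional mm^2-per-pixel factor.
#' @param manual_crop optional 0-based `c(x0, y0, x1, y1)` crop applied when
#'   automatic tray detection fails.
#' @return a `tray_config` list.
#' @export
tray_config <- function(rows = 12, cols = 12,
                        tray_filter = default_tray_filter(),
                        plant_filter = default_plant_filter(),
                        cell_px = NULL, min_blob_px = 10, margin = 0,
                        calibration = NULL, manual_crop = NULL) {
  structure(list(rows = rows, cols = cols, tray_filter = tray_filter,
                 plant_filter = plant_filter, cell_px = cell_px,
                 min_blob_px = min_blob_px, margin = margin,
                 calibration = calibration, manual_crop = manual_crop),
            class = "tray_config")
}

#' Run the full tray-measurement pipeline on one image
#'
#' Composes the six workflow steps: tray crop, tray colour filter, Hough
#' grid-line detection, grid/homography estimation, perspective rectification
#' of the original unfiltered image, per-cell segmentation, and rosette
#' measurement. Each stage logs a diagnostic line; stage failures are
#' re-thrown with the stage name.
#'
#' @param image numeric H x W x 3 array (0-255), or a PNG path.
#' @param config a [tray_config()].
#' @param image_id identifier copied into the output table.
#' @return tibble with one row per cell (`image_id`, `cell_row`, `cell_col`,
#'   `area_px`, `area_mm2`, `mean_r`, `mean_g`, `mean_b`, `n_components`);
#'   attributes `grid` (the fitted `chill_grid`) and `log` (tibble of stage
#'   diagnostics).
#' @export
process_tray <- function(image, config = tray_config(), image_id = "tray") {
  if (is.character(image)) image <- read_tray_image(image)
  log <- list()
  note <- function(stage, msg) log[[length(log) + 1L]] <<- tibble(stage = stage, message = msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cr <- stage("crop", crop_tray(image, config$tray_filter))
  if (!cr$ok) {
    if (is.null(config$manual_crop)) {
      abort(sprintf("Stage 'crop' failed: %s", cr$reason))
    }
    mc <- config$manual_crop
    cr <- list(ok = TRUE,
               image = image[(mc[2L] + 1L):(mc[4L] + 1L),
                             (mc[1L] + 1L):(mc[3L] + 1L), , drop = FALSE],
               bbox = c(mc[1L], mc[2L], mc[3L], mc[4L]),
               region = NULL)
    note("crop", "automatic crop failed; manual crop applied")
  } else {
    note("crop", sprintf("bbox x %d..%d, y %d..%d", cr$bbox[1L], cr$bbox[3L],
                         cr$bbox[2L], cr$bbox[4L]))
  }
  crop <- cr$image

  line_mask <- stage("filter", {
    tray_mask <- filter_color(crop, config$tray_filter)
    plant_mask <- filter_color(crop, config$plant_filter)
    region <- cr$region %||% matrix(TRUE, nrow(tray_mask), ncol(tray_mask))
    region & !tray_mask & !plant_mask
  })
  note("filter", sprintf("%d candidate line pixels", sum(line_mask)))

  lines <- stage("hough", detect_grid_lines(
    line_mask, expected_per_axis = c(config$rows + 1L, config$cols + 1L)))
  note("hough", sprintf("%d horizontal + %d vertical lines",
                        sum(lines$orientation == "horizontal"),
                        sum(lines$orientation == "vertical")))

  grid <- stage("grid", compute_grid(lines, dim(crop)[1:2], cell_px = config$cell_px))
  note("grid", sprintf("cell_px %d, corner RMS residual %.3f px",
                       grid$cell_px, grid$residual_px))

  reg <- stage("rectify", rectify(crop, grid))
  cells <- stage("segment", segment_cells(reg, config$rows, config$cols,
                                          cell_px = grid$cell_px,
                                          margin = config$margin))
  res <- stage("measure", {
    meas <- purrr::map(cells$image, measure_rosette,
                       plant_filter = config$plant_filter,
                       min_blob_px = config$min_blob_px,
                       calibration = config$calibration)
    dplyr::bind_cols(cells[, c("cell_row", "cell_col")], dplyr::bind_rows(meas))
  })
  note("measure", sprintf("total plant area %d px over %d cells",
                          sum(res$area_px), nrow(res)))
  out <- dplyr::bind_cols(tibble(image_id = image_id), res) |> as_tibble()
  attr(out, "grid") <- grid
  attr(out, "log") <- dplyr::bind_rows(log)
  out
}

#' Write a per-cell measurement table as CSV
#'
#' @param measurements tibble from [process_tray()].
#' @param path output CSV path.
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path)
  invisible(path)
}
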