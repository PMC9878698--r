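# Colour filtering. Images are numeric arrays H x W x 3 on 0..255 (8-bit RGB).
# Filtering in HSV is the default throughout: hue isolates the green rosette
# and the tray plastic far more robustly than raw RGB boxes do.

#' Construct colour-filter parameters
#'
#' A filter keeps pixels whose channels all lie inside the given bounds,
#' optionally followed by a morphological opening to drop speckle.
#'
#' @param space `"hsv"` (default) or `"rgb"`. In HSV, hue is in degrees
#'   (0-360) and saturation/value in 0-1; in RGB all channels are 0-255.
#' @param lower,upper length-3 numeric bounds (low <= high per channel). For
#'   hue only, `lower > upper` denotes a window wrapping through 0 degrees.
#' @param opening_px radius (pixels) of a disc opening applied to the mask;
#'   0 (default) disables it so pixel counts stay integer-exact.
#' @return a `color_filter` object.
#' @export
color_filter <- function(space = c("hsv", "rgb"), lower, upper, opening_px = 0) {
  space <- match.arg(space)
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  if (length(lower) != 3L || length(upper) != 3L) {
    abort("`lower` and `upper` must each have 3 channel bounds.")
  }
  rng <- if (space == "hsv") rbind(c(0, 360), c(0, 1), c(0, 1)) else
    rbind(c(0, 255), c(0, 255), c(0, 255))
  for (i in 1:3) {
    if (lower[i] < rng[i, 1] || upper[i] > rng[i, 2]) {
      abort(sprintf("Channel %d bounds outside the valid range [%g, %g].",
                    i, rng[i, 1], rng[i, 2]))
    }
    if (i > 1L || space == "rgb") {
      if (lower[i] > upper[i]) abort(sprintf("Channel %d: lower > upper.", i))
    }
  }
  structure(list(space = space, lower = lower, upper = upper,
                 opening_px = opening_px), class = "color_filter")
}

#' Default tray-surface filter (HSV window on the tan tray plastic)
#' @export
default_tray_filter <- function() {
  color_filter("hsv", lower = c(15, 0.2, 0.5), upper = c(60, 0.95, 1))
}

#' Default rosette filter (HSV window on healthy-leaf green)
#'
#' The lower hue bound sits at the hue of a 50/50 leaf/tray colour blend, so
#' that after bilinear rectification a boundary pixel counts as plant exactly
#' when the leaf covers at least half of it — to first order this makes the
#' measured area unbiased under resampling.
#' @export
default_plant_filter <- function() {
  color_filter("hsv", lower = c(77, 0.2, 0.1), upper = c(160, 1, 1))
}

#' Apply a colour filter to an RGB image
#'
#' @param image numeric array H x W x 3, values 0-255.
#' @param params a [color_filter()].
#' @return logical H x W mask, `TRUE` where every channel bound is met
#'   (after HSV conversion if requested), opened if configured.
#' @export
filter_color <- function(image, params) {
  if (!inherits(params, "color_filter")) abort("`params` must be a `color_filter`.")
  d <- dim(image)
  if (is.null(d) || length(d) != 3L || d[3L] != 3L) {
    abort("`image` must be a 3-channel (H x W x 3) RGB raster; grayscale input is not supported.")
  }
  h <- d[1L]; w <- d[2L]
  if (params$space == "hsv") {
    px <- rbind(as.vector(image[, , 1L]), as.vector(image[, , 2L]),
                as.vector(image[, , 3L]))
    hsv <- grDevices::rgb2hsv(px, maxColorValue = 255)
    hue <- hsv[1L, ] * 360
    lo <- params$lower; hi <- params$upper
    hue_ok <- if (lo[1L] <= hi[1L]) hue >= lo[1L] & hue <= hi[1L] else
      hue >= lo[1L] | hue <= hi[1L]
    keep <- hue_ok & hsv[2L, ] >= lo[2L] & hsv[2L, ] <= hi[2L] &
      hsv[3L, ] >= lo[3L] & hsv[3L, ] <= hi[3L]
  } else {
    lo <- params$lower; hi <- params$upper
    keep <- image[, , 1L] >= lo[1L] & image[, , 1L] <= hi[1L] &
      image[, , 2L] >= lo[2L] & image[, , 2L] <= hi[2L] &
      image[, , 3L] >= lo[3L] & image[, , 3L] <= hi[3L]
    keep <- as.vector(keep)
  }
  mask <- matrix(keep, h, w)
  if (params$opening_px > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(params$opening_px) + 1L, "disc")
    mask <- EBImage::opening(mask * 1, brush) > 0.5
  }
  mask
}
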