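test_that("colour filtering keeps exactly the in-bounds pixels", {
  plant <- default_plant_filter()
  expect_true(all(filter_color(flat_image(c(60, 140, 50)), plant)))
  expect_false(any(filter_color(flat_image(c(180, 140, 90)), plant)))
  expect_error(filter_color(matrix(0, 5, 5), plant), "3-channel")
  # a rendered disk passes the plant filter with exactly its manifest count
  spec <- small_spec()
  blob <- rosette_blob(1, 1, centers = rbind(c(20, 20)), radii = 7)
  tr <- render_tray(spec, list(blob))
  expect_equal(sum(filter_color(tr$image, plant)),
               sum(tr$manifest$pixel_count))
})

test_that("RGB-space filters and hue wraparound behave", {
  f <- color_filter("rgb", lower = c(50, 100, 0), upper = c(100, 200, 80))
  expect_true(all(filter_color(flat_image(c(60, 140, 50)), f)))
  expect_false(any(filter_color(flat_image(c(200, 140, 50)), f)))
  wrap <- color_filter("hsv", lower = c(350, 0, 0), upper = c(10, 1, 1))
  expect_true(all(filter_color(flat_image(c(255, 10, 10)), wrap)))
  expect_error(color_filter("hsv", lower = c(0, 0.5, 0), upper = c(10, 0.2, 1)),
               "lower > upper")
})

test_that("crop_tray recovers the tray extent and flags failures", {
  spec <- small_spec()
  tr <- render_tray(spec, list())
  cr <- crop_tray(tr$image)
  expect_true(cr$ok)
  w <- dim(tr$image)[2]
  truth <- c(spec$border_px, spec$border_px,
             w - spec$border_px - 1, w - spec$border_px - 1)
  expect_true(all(abs(cr$bbox - truth) <= 2))
  # blank background only: failure flag, not a silent pass-through
  blank <- flat_image(c(40, 40, 40), 100, 100)
  expect_false(crop_tray(blank)$ok)
  # tray too small in frame
  small <- flat_image(c(40, 40, 40), 100, 100)
  small[1:20, 1:20, 1] <- 180; small[1:20, 1:20, 2] <- 140; small[1:20, 1:20, 3] <- 90
  expect_false(crop_tray(small)$ok)
})

test_that("grid lines are found at the true boundaries", {
  spec <- small_spec()
  tr <- render_tray(spec, random_rosettes(spec, area_range = c(50, 300), seed = 2))
  cr <- crop_tray(tr$image)
  lm <- cr$region & !filter_color(cr$image, default_tray_filter()) &
    !filter_color(cr$image, default_plant_filter())
  ln <- detect_grid_lines(lm, c(7, 7))
  expect_equal(sum(ln$orientation == "horizontal"), 7L)
  expect_equal(sum(ln$orientation == "vertical"), 7L)
  truth <- spec$apron_px + (0:6) * spec$cell_px - 0.5
  v <- ln[ln$orientation == "vertical", ]
  h <- ln[ln$orientation == "horizontal", ]
  expect_true(all(abs(v$position - truth) <= 1))
  expect_true(all(abs(h$position - truth) <= 1))
  expect_true(all(abs(v$theta - 0) <= 0.5 * pi / 180 |
                    abs(v$theta - pi) <= 0.5 * pi / 180))
  expect_true(all(abs(h$theta - pi / 2) <= 0.5 * pi / 180))
  expect_error(detect_grid_lines(matrix(FALSE, 50, 50), 7), "Empty mask")
})

test_that("a rotated tray yields line angles at the rotation", {
  spec <- small_spec(cell_px = 40)
  spec$warp <- rotation_warp(spec, 5)
  tr <- render_tray(spec, list())
  cr <- crop_tray(tr$image)
  lm <- cr$region & !filter_color(cr$image, default_tray_filter()) &
    !filter_color(cr$image, default_plant_filter())
  ln <- detect_grid_lines(lm, c(7, 7))
  h <- ln[ln$orientation == "horizontal", ]
  # horizontal lines rotated by ~5 degrees: theta near 90 + 5
  expect_true(all(abs(h$theta * 180 / pi - 95) < 1))
})

test_that("compute_grid intersects lines exactly and flags degeneracy", {
  mk <- function(orientation, rho, theta) {
    tibble::tibble(orientation = orientation, rho = rho, theta = theta,
                   votes = 100, position = rho)
  }
  lines <- dplyr::bind_rows(
    mk("horizontal", (0:6) * 40 - 0.5, pi / 2),
    mk("vertical", (0:6) * 40 - 0.5, 0))
  g <- compute_grid(lines, c(280, 280), cell_px = 40)
  expect_equal(g$rows, 6L)
  expect_equal(g$cols, 6L)
  expect_equal(g$corners[3, 5, ], c(4 * 40 - 0.5, 2 * 40 - 0.5))
  # identity up to translation: mapping ideal corners through H is exact
  mapped <- apply_homography(g$homography, rbind(c(-0.5, -0.5), c(239.5, 239.5)))
  expect_equal(mapped, rbind(c(-0.5, -0.5), c(239.5, 239.5)), tolerance = 1e-9)
  expect_lt(g$residual_px, 1e-6)
  dup <- dplyr::bind_rows(lines, mk("vertical", 39.5, 0))
  expect_error(compute_grid(dup, c(280, 280), cell_px = 40), "Degenerate")
})

test_that("corners from a known projective warp match the forward-warped ideal corners", {
  spec <- small_spec(warp = test_warp)
  tr <- render_tray(spec, list())
  cr <- crop_tray(tr$image)
  lm <- cr$region & !filter_color(cr$image, default_tray_filter()) &
    !filter_color(cr$image, default_plant_filter())
  g <- compute_grid(detect_grid_lines(lm, c(7, 7)), dim(cr$image)[1:2],
                    cell_px = spec$cell_px)
  # ideal unwarped corner positions, forward-warped then shifted to crop coords
  g0 <- spec$border_px + spec$apron_px
  ij <- expand.grid(i = 0:6, j = 0:6)
  ideal <- cbind(g0 + ij$j * spec$cell_px - 0.5, g0 + ij$i * spec$cell_px - 0.5)
  fw <- apply_homography(tr$warp_matrix, ideal)
  fw[, 1] <- fw[, 1] - cr$bbox[1]; fw[, 2] <- fw[, 2] - cr$bbox[2]
  obs <- cbind(as.vector(g$corners[, , 1][cbind(ij$i + 1, ij$j + 1)]),
               as.vector(g$corners[, , 2][cbind(ij$i + 1, ij$j + 1)]))
  expect_lt(max(sqrt(rowSums((obs - fw)^2))), 1)
})

test_that("rectification with an identity grid reproduces the input exactly", {
  spec <- small_spec()
  tr <- render_tray(spec, random_rosettes(spec, area_range = c(50, 300), seed = 4))
  cr <- crop_tray(tr$image)
  lm <- cr$region & !filter_color(cr$image, default_tray_filter()) &
    !filter_color(cr$image, default_plant_filter())
  g <- compute_grid(detect_grid_lines(lm, c(7, 7)), dim(cr$image)[1:2],
                    cell_px = spec$cell_px)
  reg <- rectify(cr$image, g)
  # the rectified frame is the grid area of the crop, shifted by the apron
  a <- spec$apron_px
  expect_equal(reg, cr$image[(a + 1):(a + 240), (a + 1):(a + 240), ])
})

test_that("rectifying a warped tray recovers blob centroids within 1.5 px", {
  spec <- small_spec(cell_px = 40, warp = test_warp)
  ros <- random_rosettes(spec, area_range = c(100, 500), seed = 9)
  tr <- render_tray(spec, ros)
  cr <- crop_tray(tr$image)
  lm <- cr$region & !filter_color(cr$image, default_tray_filter()) &
    !filter_color(cr$image, default_plant_filter())
  g <- compute_grid(detect_grid_lines(lm, c(7, 7)), dim(cr$image)[1:2],
                    cell_px = spec$cell_px)
  reg <- rectify(cr$image, g)
  mask <- filter_color(reg, default_plant_filter())
  # per-cell centroid vs the unwarped render's centroid
  un <- render_tray(small_spec(cell_px = 40), ros)
  mask0 <- filter_color(un$image, default_plant_filter())
  g0 <- spec$border_px + spec$apron_px
  errs <- purrr::map_dbl(ros, function(b) {
    cells_r <- b$cell_row * 40 + seq_len(40)
    cells_c <- b$cell_col * 40 + seq_len(40)
    m1 <- mask[cells_r, cells_c]
    m0 <- mask0[g0 + b$cell_row * 40 + seq_len(40), g0 + b$cell_col * 40 + seq_len(40)]
    c1 <- which(m1, arr.ind = TRUE); c0 <- which(m0, arr.ind = TRUE)
    sqrt(sum((colMeans(c1) - colMeans(c0))^2))
  })
  expect_lt(max(errs), 1.5)
})

test_that("segmentation partitions the rectified frame", {
  img <- array(runif(120 * 120 * 3) * 255, dim = c(120, 120, 3))
  cells <- segment_cells(img, rows = 3, cols = 3, cell_px = 40)
  expect_equal(nrow(cells), 9L)
  expect_true(all(purrr::map_lgl(cells$image, ~ all(dim(.x) == c(40, 40, 3)))))
  # row-major order and exact partition: reassembling recovers the image
  rebuilt <- array(NA_real_, dim = dim(img))
  for (k in seq_len(nrow(cells))) {
    r <- cells$cell_row[k] * 40 + 1:40
    c <- cells$cell_col[k] * 40 + 1:40
    expect_true(all(is.na(rebuilt[r, c, ])))
    rebuilt[r, c, ] <- cells$image[[k]]
  }
  expect_identical(rebuilt, img)
  with_margin <- segment_cells(img, 3, 3, cell_px = 40, margin = 2)
  expect_true(all(purrr::map_lgl(with_margin$image, ~ all(dim(.x)[1:2] == 36))))
})

test_that("measure_rosette despeckles and aggregates all retained components", {
  cp <- 40
  empty <- flat_image(c(180, 140, 90), cp, cp)
  m0 <- measure_rosette(empty)
  expect_equal(m0$area_px, 0L)
  expect_equal(m0$n_components, 0L)
  expect_true(is.na(m0$mean_r))
  # two blobs of 100 and 15 px, despeckle at 20 keeps only the large one
  img <- flat_image(c(180, 140, 90), cp, cp)
  green <- c(60, 140, 50)
  px100 <- cbind(rep(5:14, each = 10), rep(5:14, times = 10))
  px15 <- cbind(rep(30:34, each = 3), rep(25:27, times = 5))
  for (ch in 1:3) {
    img[cbind(px100, ch)] <- green[ch]
    img[cbind(px15, ch)] <- green[ch]
  }
  m <- measure_rosette(img, min_blob_px = 20)
  expect_equal(m$area_px, 100L)
  expect_equal(m$n_components, 1L)
  m2 <- measure_rosette(img, min_blob_px = 10)
  expect_equal(m2$area_px, 115L)
  expect_equal(m2$n_components, 2L)
  expect_equal(c(m2$mean_r, m2$mean_g, m2$mean_b), green)
  # calibration converts to mm^2
  expect_equal(measure_rosette(img, min_blob_px = 20, calibration = 0.25)$area_mm2, 25)
})

test_that("components are 8-connected: a diagonal chain is one blob", {
  cp <- 20
  img <- flat_image(c(180, 140, 90), cp, cp)
  green <- c(60, 140, 50)
  for (k in 0:11) for (ch in 1:3) img[5 + k, 5 + k, ch] <- green[ch]
  m <- measure_rosette(img, min_blob_px = 10)
  expect_equal(m$n_components, 1L)
  expect_equal(m$area_px, 12L)
})

test_that("the unwarped pipeline is integer-exact against the manifest", {
  spec <- small_spec()
  tr <- render_tray(spec, random_rosettes(spec, area_range = c(50, 600), seed = 14))
  res <- process_tray(tr$image, tray_config(rows = 6, cols = 6, cell_px = 40))
  m <- dplyr::inner_join(res, tr$manifest, by = c("cell_row", "cell_col"))
  expect_identical(as.integer(m$area_px), as.integer(m$pixel_count))
})

test_that("the warped pipeline stays within interpolation tolerance of ground truth", {
  spec <- small_spec(warp = test_warp)
  tr <- render_tray(spec, random_rosettes(spec, area_range = c(100, 900), seed = 15))
  res <- process_tray(tr$image, tray_config(rows = 6, cols = 6, cell_px = 40))
  m <- dplyr::inner_join(res, tr$manifest, by = c("cell_row", "cell_col"))
  expect_gt(cor(m$area_px, m$pixel_count), 0.99)
  rel <- abs(m$area_px - m$pixel_count) / m$pixel_count
  expect_lt(mean(rel), 0.02)
})

test_that("pipeline partition: cell areas sum to the whole-frame plant count", {
  spec <- small_spec()
  tr <- render_tray(spec, random_rosettes(spec, area_range = c(50, 400), seed = 16))
  cfg <- tray_config(rows = 6, cols = 6, cell_px = 40, min_blob_px = 1)
  res <- process_tray(tr$image, cfg)
  expect_identical(sum(res$area_px), sum(tr$manifest$pixel_count))
})

test_that("measured area is monotone in blob size", {
  spec <- small_spec()
  grow <- function(r) {
    tr <- render_tray(spec, list(rosette_blob(2, 2, rbind(c(20, 20)), r)))
    res <- process_tray(tr$image, tray_config(rows = 6, cols = 6, cell_px = 40))
    res$area_px[res$cell_row == 2 & res$cell_col == 2]
  }
  areas <- vapply(c(3, 5, 8, 11), grow, integer(1))
  expect_true(all(diff(areas) > 0))
})

test_that("manual crop rescues a frame the automatic crop rejects", {
  spec <- small_spec(border_px = 0)
  tr <- render_tray(spec, list(rosette_blob(0, 0, rbind(c(20, 20)), 6)))
  # bury the tray in a frame dominated by background so auto-crop fails
  big <- flat_image(c(40, 40, 40), 1300, 1300)
  big[1:nrow(tr$image), 1:ncol(tr$image), ] <- tr$image
  cfg <- tray_config(rows = 6, cols = 6, cell_px = 40)
  expect_error(process_tray(big, cfg), "crop")
  cfg$manual_crop <- c(0, 0, ncol(tr$image) - 1, nrow(tr$image) - 1)
  res <- process_tray(big, cfg)
  expect_equal(sum(res$area_px), sum(tr$manifest$pixel_count))
})
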