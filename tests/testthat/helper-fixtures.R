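# Shared builders for the test suite. Everything is generated in code; no
# binary fixtures.

# a small tray spec that keeps unit tests fast
small_spec <- function(rows = 6, cols = 6, cell_px = 40, ...) {
  tray_spec(rows = rows, cols = cols, cell_px = cell_px, ...)
}

# count the pixels of a disk union by brute force on the cell lattice —
# independent oracle for blob areas
disk_union_pixels <- function(centers, radii, cell_px) {
  n <- 0L
  for (u in 0:(cell_px - 1L)) for (v in 0:(cell_px - 1L)) {
    for (d in seq_along(radii)) {
      if ((u - centers[d, 1L])^2 + (v - centers[d, 2L])^2 <= radii[d]^2) {
        n <- n + 1L
        break
      }
    }
  }
  n
}

# corner displacements approximating a rotation by `deg` about the centre
rotation_warp <- function(spec, deg) {
  W <- 2 * (spec$border_px + spec$apron_px) + spec$cols * spec$cell_px
  H <- 2 * (spec$border_px + spec$apron_px) + spec$rows * spec$cell_px
  th <- deg * pi / 180
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  corners <- rbind(c(0, 0), c(W - 1, 0), c(W - 1, H - 1), c(0, H - 1))
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  rot <- t(R %*% t(sweep(corners, 2, ctr))) + rep(ctr, each = 4)
  # shrink towards the centre so the rotated tray stays inside the frame
  rot <- sweep(sweep(rot, 2, ctr), 2, c(0.9, 0.9), "*") + rep(ctr, each = 4)
  rot - corners
}

# a mild but clearly projective warp (used across imaging tests)
test_warp <- rbind(c(15, 10), c(-12, 18), c(14, -16), c(-8, -12))

# uniform-colour image helper
flat_image <- function(color, h = 20, w = 20) {
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- color[ch]
  img
}
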