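# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no binary fixtures.

iou <- function(a, b) sum(a & b) / sum(a | b)

# Independent rasterizer for a filled ellipse (centre-sampling), written
# directly from the quadratic form rather than via the package helpers.
raster_ellipse <- function(shape, center, a, b, theta = 0) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) {
    dy <- (r - 1) - center[1]
    dc <- (seq_len(shape[2]) - 1) - center[2]
    x <- dc * cos(theta) + dy * sin(theta)
    y <- -dc * sin(theta) + dy * cos(theta)
    m[r, ] <- (x / a)^2 + (y / b)^2 <= 1
  }
  m
}

# Two-valued blob image: union of 2-4 random ellipses all overlapping the
# grid centre (star-shaped, hence simply connected), dark blob on bright
# background.
make_blob_image <- function(seed, n = 64L, lo = 40, hi = 200) {
  set.seed(seed)
  ctr <- c(n, n) / 2
  mask <- matrix(FALSE, n, n)
  for (k in seq_len(sample(2:4, 1))) {
    a <- runif(1, 6, 16)
    b <- runif(1, 4, a)
    th <- runif(1, 0, pi)
    cen <- ctr + runif(2, -4, 4)
    mask <- mask | raster_ellipse(c(n, n), cen, a, b, th)
  }
  img <- matrix(hi, n, n)
  img[mask] <- lo
  list(image = img, mask = mask)
}

# Random polyomino grown by a seeded random walk from the grid centre.
random_polyomino <- function(seed, ncells = 60L, n = 48L) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  pos <- floor(c(n, n) / 2)
  m[pos[1], pos[2]] <- TRUE
  steps <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  placed <- 1L
  while (placed < ncells) {
    s <- steps[sample(4L, 1L), ]
    cand <- pmin(pmax(pos + s, 2L), n - 1L)
    pos <- cand
    if (!m[pos[1], pos[2]]) placed <- placed + 1L
    m[pos[1], pos[2]] <- TRUE
  }
  m
}

# Independent solidity oracle: convex-hull polygon of the pixel centres
# (grDevices::chull) filled by an independent point-in-polygon routine
# (sp::point.in.polygon, even-odd crossing test) rather than the package's
# half-plane rasterizer; region area = pixel count.
oracle_solidity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[h, , drop = FALSE]
  rr <- range(pts[, 1]); cr <- range(pts[, 2])
  grid <- expand.grid(row = rr[1]:rr[2], col = cr[1]:cr[2])
  inside <- sp::point.in.polygon(grid$col, grid$row, hp[, 2], hp[, 1])
  hull_px <- sum(inside > 0)
  nrow(idx) / max(hull_px, nrow(idx))
}

# Plus shape: 3x3 arrangement of 10x10 blocks minus the corners, on a
# padded grid. Continuous hull area 700 vs region area 500.
plus_shape <- function(block = 10L, pad = 6L) {
  n <- 3L * block + 2L * pad
  m <- matrix(FALSE, n, n)
  on <- function(bi, bj) {
    rows <- pad + (bi - 1L) * block + seq_len(block)
    cols <- pad + (bj - 1L) * block + seq_len(block)
    m[rows, cols] <<- TRUE
  }
  on(1, 2); on(2, 1); on(2, 2); on(2, 3); on(3, 2)
  m
}

# Dumbbell: two 20x20 blocks joined by a 2 px wide, 10 px long bridge.
dumbbell <- function(pad = 6L) {
  h <- 20L + 2L * pad
  w <- 2L * 20L + 10L + 2L * pad
  m <- matrix(FALSE, h, w)
  m[pad + 1:20, pad + 1:20] <- TRUE                  # block A
  m[pad + 1:20, pad + 30 + 1:20] <- TRUE             # block B
  m[pad + 10:11, pad + 20 + 1:10] <- TRUE            # bridge
  m
}

# Shoelace polygon area for (row, col) point matrices.
shoelace_area <- function(pts) {
  n <- nrow(pts)
  nxt <- c(2:n, 1L)
  abs(0.5 * sum(pts[, 1] * pts[nxt, 2] - pts[nxt, 1] * pts[, 2]))
}

default_dark_image <- function(seed = 1, ...) {
  render_stoma(stoma_spec(seed = seed, ...))
}

region_centroid_test <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  colMeans(idx) - 1
}
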