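# Binary-mask operations on the segmented pore: connected components,
# solidity-based independence discrimination, morphological disconnection,
# hole filling and sub-pixel boundary extraction.
#
# Connectivity convention: 8-connected foreground, 4-connected background.

#' Label connected components of a binary mask
#'
#' Iterative minimum-label propagation: every foreground pixel starts with
#' its own label and repeatedly adopts the smallest label among itself and
#' its neighbours until stable. Components are then renumbered 1, 2, ... in
#' order of their smallest pixel (column-major) index.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default, foreground) or 4 (background duality).
#' @return integer matrix; 0 = background, k = k-th component.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask) || !is.logical(mask)) stop_invalid("mask must be a logical matrix")
  if (!connectivity %in% c(4L, 8L)) stop_invalid("connectivity must be 4 or 8")
  lab <- matrix(Inf, nrow(mask), ncol(mask))
  lab[mask] <- which(mask)
  offs <- list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
  }
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift_pad(lab, o[1], o[2], Inf))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  roots <- sort(unique(lab[mask]))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask] <- match(lab[mask], roots)
  out
}

region_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)  # 0-based (row, col)
}

#' Select the pore component nearest the ROI centre
#'
#' The pore is assumed to lie near the centre of the region of interest.
#' Returns the 8-connected component containing `center` if one does, else
#' the component whose centroid is nearest to `center` (ties broken by
#' larger area, then smaller label).
#'
#' @param mask logical matrix.
#' @param center `c(row, col)`, 0-based; `NULL` uses the grid centre.
#' @return logical matrix holding exactly one component.
#' @export
select_central_region <- function(mask, center = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) stop_invalid("mask must be a logical matrix")
  if (!any(mask)) stop_stomapore("empty_segmentation", "mask has no foreground")
  if (is.null(center)) center <- floor(dim(mask) / 2)
  lab <- label_components(mask, 8L)
  at <- lab[round(center[1]) + 1L, round(center[2]) + 1L]
  if (at > 0L) return(lab == at)
  k <- max(lab)
  stats <- vapply(seq_len(k), function(i) {
    m <- lab == i
    cen <- region_centroid(m)
    c(dist = sqrt(sum((cen - center)^2)), area = sum(m))
  }, numeric(2))
  ord <- order(stats["dist", ], -stats["area", ], seq_len(k))
  lab == ord[1L]
}

# Convex hull polygon of the foreground pixel centres, as a 2-column
# (row, col) matrix in chull() order. Centre-based (not pixel-corner-based),
# so convex digital shapes are their own hulls up to corner chamfers and a
# digital ellipse keeps solidity ~1.
region_hull_polygon <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind(idx[, 1] - 1, idx[, 2] - 1)
  h <- grDevices::chull(pts[, 2], pts[, 1])  # (x = col, y = row)
  pts[h, , drop = FALSE]
}

# Count pixel centres inside (or on) a convex polygon, restricted to the
# region's bounding box. Vectorized half-plane tests.
count_centres_in_convex <- function(poly, rrange, crange) {
  rows <- rrange[1]:rrange[2]
  cols <- crange[1]:crange[2]
  R <- matrix(rows, length(rows), length(cols))
  C <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  n <- nrow(poly)
  # polygon orientation via shoelace on (x = col, y = row)
  nxt <- c(2:n, 1L)
  area2 <- sum(poly[, 2] * poly[nxt, 1] - poly[nxt, 2] * poly[, 1])
  s <- sign(area2)
  if (s == 0) s <- 1
  inside <- matrix(TRUE, length(rows), length(cols))
  for (i in seq_len(n)) {
    j <- nxt[i]
    cross <- (poly[j, 2] - poly[i, 2]) * (R - poly[i, 1]) -
             (poly[j, 1] - poly[i, 1]) * (C - poly[i, 2])
    inside <- inside & (s * cross >= -1e-9)
  }
  sum(inside)
}

#' Solidity and independence of a pore region
#'
#' Solidity = Area / Convex Area, where Convex Area is the pixel count of the
#' filled convex hull of the region. A region is classified *independent*
#' (a clean, isolated pore) when solidity >= `threshold` (default 0.85);
#' below that the region is considered connected to other structures and a
#' morphological disconnection step is warranted.
#'
#' @param region logical matrix holding exactly one 8-connected component.
#' @param threshold independence threshold on solidity (default 0.85;
#'   solidity exactly at the threshold counts as independent).
#' @return an object of class `shape_report`: list with `area_px`,
#'   `convex_area_px`, `solidity`, `independent`, `centroid` (0-based
#'   `c(row, col)`), `touches_border`.
#' @export
region_solidity <- function(region, threshold = 0.85) {
  if (!is.matrix(region) || !is.logical(region)) stop_invalid("region must be a logical matrix")
  if (!any(region)) stop_stomapore("empty_segmentation", "region is empty")
  lab <- label_components(region, 8L)
  if (max(lab) > 1L) stop_invalid("region must contain exactly one connected component")
  idx <- which(region, arr.ind = TRUE)
  area <- nrow(idx)
  poly <- region_hull_polygon(region)
  hull_px <- count_centres_in_convex(
    poly,
    rrange = range(idx[, 1] - 1),
    crange = range(idx[, 2] - 1)
  )
  hull_px <- max(hull_px, area)  # discretization can never make the hull smaller
  sol <- min(1, area / hull_px)
  structure(list(
    area_px = area,
    convex_area_px = hull_px,
    solidity = sol,
    independent = sol >= threshold,
    centroid = region_centroid(region),
    touches_border = any(region[1, ]) || any(region[nrow(region), ]) ||
      any(region[, 1]) || any(region[, ncol(region)])
  ), class = "shape_report")
}

erode_mask <- function(mask, radius) {
  offs <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    out <- out & shift_pad(mask, offs$dr[i], offs$dc[i], FALSE)
  }
  out
}

dilate_mask <- function(mask, radius) {
  offs <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(offs))) {
    out <- out | shift_pad(mask, offs$dr[i], offs$dc[i], FALSE)
  }
  out
}

#' Disconnect a non-independent pore region
#'
#' When the segmented pore is fused with neighbouring structures
#' (solidity < threshold), erosion with a disk breaks thin bridges, the
#' central component is re-selected, dilated back with the same disk and
#' restricted to the original footprint. The disk radius starts at
#' `se_radius` and grows by 1 px per round, up to `max_rounds` rounds, until
#' the region is independent.
#'
#' @param region logical matrix (single 8-connected component).
#' @param center `c(row, col)` 0-based pore seed; `NULL` = grid centre.
#' @param se_radius starting disk radius in pixels (default 2).
#' @param max_rounds maximum erosion/dilation rounds (default 3).
#' @param threshold solidity threshold (default 0.85).
#' @return logical matrix of the disconnected region, with attributes
#'   `rounds` (rounds used; 0 if the input was already independent) and
#'   `shape` (the final [region_solidity()] report).
#' @export
disconnect_region <- function(region, center = NULL, se_radius = 2,
                              max_rounds = 3L, threshold = 0.85) {
  if (!any(region)) stop_stomapore("empty_segmentation", "region is empty")
  if (is.null(center)) center <- floor(dim(region) / 2)
  rep0 <- region_solidity(region, threshold)
  if (rep0$independent) {
    attr(region, "rounds") <- 0L
    attr(region, "shape") <- rep0
    return(region)
  }
  footprint <- region
  current <- region
  radius <- se_radius
  rep_cur <- rep0
  rounds <- 0L
  for (round in seq_len(max_rounds)) {
    er <- erode_mask(current, radius)
    if (!any(er)) {
      stop_stomapore("disconnect_failed",
        sprintf("erosion with disk radius %g removed all foreground", radius))
    }
    core <- select_central_region(er, center)
    di <- dilate_mask(core, radius) & footprint
    current <- select_central_region(di, center)
    rounds <- round
    rep_cur <- region_solidity(current, threshold)
    if (rep_cur$independent) break
    radius <- radius + 1
  }
  attr(current, "rounds") <- rounds
  attr(current, "shape") <- rep_cur
  current
}

#' Fill interior holes of a region
#'
#' Background components not 4-connected to the grid border become
#' foreground. Idempotent.
#'
#' @param region logical matrix.
#' @return logical matrix with holes filled.
#' @export
fill_holes <- function(region) {
  if (!is.matrix(region) || !is.logical(region)) stop_invalid("region must be a logical matrix")
  if (!any(region)) return(region)
  bg <- label_components(!region, 4L)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  out <- region | (!region & !(bg %in% border_labels))
  dim(out) <- dim(region)
  out
}

#' Extract the sub-pixel outer boundary of a region
#'
#' Traces the 0.5 iso-level of the (zero-padded) binary mask with linear
#' interpolation, so the boundary runs half a pixel outside the foreground
#' centres and corners are chamfered rather than stair-stepped. The outer
#' contour (largest enclosed area) is returned, oriented counter-clockwise
#' in (row, col) and rotated to start at the topmost, then leftmost point.
#'
#' @param region logical matrix, one filled component, at least 9 pixels.
#' @return an n x 2 matrix with columns `row`, `col` (0-based, sub-pixel);
#'   the polygon is closed implicitly (last point connects to the first).
#' @export
extract_boundary <- function(region) {
  if (!is.matrix(region) || !is.logical(region)) stop_invalid("region must be a logical matrix")
  if (sum(region) < 9L) {
    stop_stomapore("too_small_region", "region has fewer than 9 pixels")
  }
  nr <- nrow(region); nc <- ncol(region)
  z <- matrix(0, nr + 2L, nc + 2L)
  z[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(region)
  # grid coordinates such that original pixel (r, c) sits at (r, c) 0-based
  xs <- (0:(nr + 1L)) - 1
  ys <- (0:(nc + 1L)) - 1
  cl <- grDevices::contourLines(xs, ys, z, levels = 0.5)
  if (length(cl) == 0L) stop_stomapore("too_small_region", "no iso-contour found")
  shoelace <- function(r, c) {
    n <- length(r)
    nxt <- c(2:n, 1L)
    0.5 * sum(r * c[nxt] - r[nxt] * c)
  }
  areas <- vapply(cl, function(ct) abs(shoelace(ct$x, ct$y)), numeric(1))
  ct <- cl[[which.max(areas)]]
  r <- ct$x; c <- ct$y
  if (length(r) > 1 && r[1] == r[length(r)] && c[1] == c[length(c)]) {
    r <- r[-length(r)]; c <- c[-length(c)]
  }
  # orient counter-clockwise in (row, col): positive shoelace area
  if (shoelace(r, c) < 0) {
    r <- rev(r); c <- rev(c)
  }
  # start at topmost-then-leftmost point
  start <- order(r, c)[1L]
  if (start > 1L) {
    ix <- c(start:length(r), 1:(start - 1L))
    r <- r[ix]; c <- c[ix]
  }
  cbind(row = r, col = c)
}
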