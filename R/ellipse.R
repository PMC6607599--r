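# Ellipse fitting of the extracted pore boundary.
#
# Orientation convention: theta in [0, pi) is the angle of the major axis
# measured from the column (x) axis toward the row (y) axis. Points are
# (row, col) matrices as produced by extract_boundary().

#' Ellipse parameters
#'
#' @param center `c(row, col)`, sub-pixel.
#' @param a semi-major axis, px.
#' @param b semi-minor axis, px (`a >= b > 0` enforced by swapping and
#'   rotating `theta` by pi/2 when needed).
#' @param theta major-axis orientation in radians, normalized to `[0, pi)`.
#' @return an object of class `ellipse_params`.
#' @export
ellipse_params <- function(center, a, b, theta = 0) {
  if (length(center) != 2 || !all(is.finite(center))) stop_invalid("center must be c(row, col)")
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a <= 0) {
    stop_invalid("axes must be finite and positive")
  }
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    theta <- theta + pi / 2
  }
  theta <- theta %% pi
  structure(list(center = as.numeric(center), a = a, b = b, theta = theta),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("Ellipse: centre (%.2f, %.2f), a = %.3f px, b = %.3f px, theta = %.1f deg\n",
              x$center[1], x$center[2], x$a, x$b, x$theta * 180 / pi))
  invisible(x)
}

#' Sample points on an ellipse
#'
#' Parametric sampling, mainly for tests and mask rasterization checks.
#'
#' @param ellipse an [ellipse_params()] object.
#' @param n number of points.
#' @return an n x 2 (row, col) matrix.
#' @export
ellipse_points <- function(ellipse, n = 64L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ct <- cos(ellipse$theta); st <- sin(ellipse$theta)
  col <- ellipse$center[2] + ellipse$a * ct * cos(t) - ellipse$b * st * sin(t)
  row <- ellipse$center[1] + ellipse$a * st * cos(t) + ellipse$b * ct * sin(t)
  cbind(row = row, col = col)
}

#' Direct least-squares ellipse fit
#'
#' Fits the conic `A x^2 + B x y + C y^2 + D x + E y + F = 0` constrained to
#' an ellipse (4AC - B^2 > 0) by the numerically stable partitioned
#' eigensystem formulation of the direct least-squares method, then converts
#' to canonical centre/axes/orientation form. Input coordinates are centred
#' and scaled before fitting, which makes the result invariant to
#' translation, rotation and uniform scaling of the points.
#'
#' @param points n x 2 (row, col) matrix, n >= 5, not collinear.
#' @return an [ellipse_params()] object.
#' @export
fit_ellipse <- function(points) {
  if (!is.matrix(points) || ncol(points) != 2) stop_invalid("points must be an n x 2 matrix")
  pts <- unique(points)
  if (nrow(pts) < 5L) {
    stop_stomapore("fit_failed", "at least 5 distinct points are required")
  }
  x <- pts[, 2]; y <- pts[, 1]  # x = col, y = row
  mx <- mean(x); my <- mean(y)
  sc <- mean(sqrt((x - mx)^2 + (y - my)^2))
  if (sc < 1e-12) stop_stomapore("fit_failed", "degenerate point configuration")
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T1 <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T1)) stop_stomapore("fit_failed", "degenerate (possibly collinear) points")
  M <- S1 + S2 %*% T1
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  ok <- which(apply(ev$vectors, 2, function(v) {
    val <- 4 * v[1] * v[3] - v[2]^2
    is.finite(val) && Re(val) > 0 && all(abs(Im(v)) < 1e-10)
  }))
  if (length(ok) == 0L) stop_stomapore("fit_failed", "no ellipse satisfies the conic fit")
  a1 <- Re(ev$vectors[, ok[1L]])
  coef <- c(a1, as.numeric(T1 %*% a1))  # A, B, C, D, E, F in scaled frame
  # undo the normalization: substitute xs = (x - mx)/sc, ys = (y - my)/sc
  A <- coef[1] / sc^2
  B <- coef[2] / sc^2
  C <- coef[3] / sc^2
  D <- coef[4] / sc - 2 * A * mx - B * my
  E <- coef[5] / sc - 2 * C * my - B * mx
  Ff <- coef[6] + A * mx^2 + B * mx * my + C * my^2 -
    coef[4] * mx / sc - coef[5] * my / sc
  conic_to_ellipse(c(A, B, C, D, E, Ff))
}

# Convert conic coefficients (A, B, C, D, E, F) with x = col, y = row into
# canonical ellipse_params.
conic_to_ellipse <- function(k) {
  A <- k[1]; B <- k[2]; C <- k[3]; D <- k[4]; E <- k[5]; Ff <- k[6]
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  det_q <- det(Q)
  if (!is.finite(det_q) || det_q <= 0) {
    stop_stomapore("fit_failed", "conic is not an ellipse")
  }
  cen_xy <- solve(2 * Q, -c(D, E))  # (x0, y0)
  c0 <- A * cen_xy[1]^2 + B * cen_xy[1] * cen_xy[2] + C * cen_xy[2]^2 +
    D * cen_xy[1] + E * cen_xy[2] + Ff
  eg <- eigen(Q, symmetric = TRUE)
  semi2 <- -c0 / eg$values
  if (any(!is.finite(semi2)) || any(semi2 <= 0)) {
    stop_stomapore("fit_failed", "conic is not a real ellipse")
  }
  semi <- sqrt(semi2)  # semi-axis along each eigenvector
  imax <- which.max(semi)
  v <- eg$vectors[, imax]  # (x, y) direction of the major axis
  theta <- atan2(v[2], v[1])
  ellipse_params(center = c(cen_xy[2], cen_xy[1]), a = max(semi), b = min(semi),
                 theta = theta)
}

#' Moment-based ellipse of a region
#'
#' Fallback fitter: derives centre, axes and orientation from the region's
#' second-order central moments (with the 1/12 unit-square correction), then
#' rescales the axes so the ellipse area equals the region's pixel area.
#' Always succeeds on a region of at least 9 pixels.
#'
#' @param region logical matrix, >= 9 foreground pixels.
#' @return an [ellipse_params()] object.
#' @export
ellipse_from_moments <- function(region) {
  if (!is.matrix(region) || !is.logical(region)) stop_invalid("region must be a logical matrix")
  npix <- sum(region)
  if (npix < 9L) stop_stomapore("too_small_region", "region has fewer than 9 pixels")
  idx <- which(region, arr.ind = TRUE)
  y <- idx[, 1] - 1  # row
  x <- idx[, 2] - 1  # col
  mx <- mean(x); my <- mean(y)
  # 1/12 is the variance of a unit pixel, so single-row regions stay proper
  m20 <- mean((x - mx)^2) + 1 / 12
  m02 <- mean((y - my)^2) + 1 / 12
  m11 <- mean((x - mx) * (y - my))
  Cm <- matrix(c(m20, m11, m11, m02), 2, 2)
  eg <- eigen(Cm, symmetric = TRUE)
  a0 <- 2 * sqrt(max(eg$values[1], 1e-12))
  b0 <- 2 * sqrt(max(eg$values[2], 1e-12))
  s <- sqrt(npix / (pi * a0 * b0))
  v <- eg$vectors[, 1]
  ellipse_params(center = c(my, mx), a = a0 * s, b = b0 * s,
                 theta = atan2(v[2], v[1]))
}
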