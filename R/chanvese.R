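# Chan-Vese two-phase level-set segmentation.
#
# The contour C is the zero crossing of a signed field phi (phi > 0 inside C,
# phi < 0 outside). The energy being minimized is
#
#   E(C, c1, c2) = mu * Length(C) + nu * Area(inside(C))
#                + lambda1 * sum_{outside(C)} |I - c1|^p
#                + lambda2 * sum_{inside(C)}  |I - c2|^p
#
# with c1 the mean intensity outside C, c2 the mean inside, and p = 2 by
# default (the classical piecewise-constant model; p is configurable).
# Length and Area are computed from a smoothed Heaviside of phi so the
# gradient flow is well defined on the discrete grid.

#' Chan-Vese parameters
#'
#' Bundles the weights and numerical settings of the level-set evolution.
#'
#' @param mu length-penalty weight. `NULL` (default) resolves at segmentation
#'   time to `0.1 * (intensity range)^2`, which scales the curvature force to
#'   the squared-intensity units of the fitting terms.
#' @param nu area-penalty weight (default 0: no bias toward shrinking).
#' @param lambda1 weight of the outside fitting term (must be > 0).
#' @param lambda2 weight of the inside fitting term (must be > 0).
#' @param max_iters iteration budget (default 300).
#' @param dt explicit time step (default 0.5).
#' @param epsilon Heaviside/Dirac smoothing width in pixels (default 1).
#' @param tol stopping tolerance: the evolution stops once the fraction of
#'   pixels whose sign changed in one iteration falls below `tol`.
#' @param init_radius radius in pixels of the initial circular contour;
#'   `NULL` defaults to `min(height, width) / 8`.
#' @param fit_exponent exponent p of the fitting terms `|I - c|^p`
#'   (default 2, the squared-difference form).
#' @return an object of class `cv_params`.
#' @export
cv_params <- function(mu = NULL, nu = 0, lambda1 = 1, lambda2 = 1,
                      max_iters = 300L, dt = 0.5, epsilon = 1,
                      tol = 1e-4, init_radius = NULL, fit_exponent = 2) {
  if (!is.null(mu) && (!is.finite(mu) || mu < 0)) stop_invalid("mu must be >= 0")
  if (!is.finite(nu)) stop_invalid("nu must be finite")
  if (lambda1 <= 0 || lambda2 <= 0) stop_invalid("lambda1 and lambda2 must be > 0")
  if (max_iters < 1) stop_invalid("max_iters must be >= 1")
  if (dt < 0) stop_invalid("dt must be >= 0")
  if (epsilon <= 0) stop_invalid("epsilon must be > 0")
  if (fit_exponent <= 0) stop_invalid("fit_exponent must be > 0")
  structure(list(
    mu = mu, nu = nu, lambda1 = lambda1, lambda2 = lambda2,
    max_iters = as.integer(max_iters), dt = dt, epsilon = epsilon,
    tol = tol, init_radius = init_radius, fit_exponent = fit_exponent
  ), class = "cv_params")
}

# mu = NULL means "scale with the image": 0.1 * (intensity range)^2.
resolve_mu <- function(params, image) {
  if (!is.null(params$mu)) return(params$mu)
  0.1 * diff(range(image))^2
}

heaviside_eps <- function(phi, epsilon) 0.5 * (1 + (2 / pi) * atan(phi / epsilon))

dirac_eps <- function(phi, epsilon) (epsilon / pi) / (epsilon^2 + phi^2)

#' Initialize the level set as a circle
#'
#' Builds the signed distance to a circle, positive inside, so the contour
#' starts as a small circle at (by default) the centre of the region of
#' interest — the only prior the method uses about the pore.
#'
#' @param dim integer vector `c(height, width)` of the grid.
#' @param center `c(row, col)` of the circle centre, 0-based pixel
#'   coordinates; `NULL` uses the grid centre `floor(dim / 2)`.
#' @param radius circle radius in pixels, `2 <= radius < min(dim) / 2`;
#'   `NULL` uses `min(dim) / 8`.
#' @return a numeric matrix `phi` with `phi > 0` inside the circle.
#' @export
initialize_phi <- function(dim, center = NULL, radius = NULL) {
  if (length(dim) != 2 || any(dim < 1)) stop_invalid("dim must be two positive sizes")
  if (is.null(center)) center <- floor(dim / 2)
  if (is.null(radius)) radius <- min(dim) / 8
  if (length(center) != 2 || center[1] < 0 || center[1] > dim[1] - 1 ||
      center[2] < 0 || center[2] > dim[2] - 1) {
    stop_invalid("center must lie inside the grid")
  }
  if (radius < 2 || radius >= min(dim) / 2) {
    stop_invalid("radius must satisfy 2 <= radius < min(dim) / 2")
  }
  rows <- seq_len(dim[1]) - 1
  cols <- seq_len(dim[2]) - 1
  dr2 <- (rows - center[1])^2
  dc2 <- (cols - center[2])^2
  radius - sqrt(outer(dr2, dc2, `+`))
}

#' Mean intensities of the two phases
#'
#' `c2` is the mean of the image over the inside phase (`phi > 0`, the
#' region grown from the centre seed), `c1` the mean over the outside phase
#' (`phi <= 0`).
#'
#' @param image grayscale matrix.
#' @param phi level-set matrix of the same dimensions.
#' @return a list with elements `c1` (outside mean) and `c2` (inside mean).
#' @export
region_means <- function(image, phi) {
  if (!all(dim(image) == dim(phi))) stop_invalid("image and phi dimensions differ")
  inside <- phi > 0
  n_in <- sum(inside)
  if (n_in == 0L || n_in == length(phi)) {
    stop_stomapore("degenerate_level_set", "level set has a single sign: one phase is empty")
  }
  list(c1 = mean(image[!inside]), c2 = mean(image[inside]))
}

#' Chan-Vese energy of a configuration
#'
#' Evaluates `mu * Length(C) + nu * Area(inside(C))` plus the two fitting
#' sums, with Length and Area taken from the smoothed Heaviside of `phi`
#' (Length as the grid sum of `|grad H_eps(phi)|` by central differences)
#' and the fitting sums taken sharply over the sign classes of `phi`.
#'
#' @inheritParams region_means
#' @param params a [cv_params()] object.
#' @param stats optional precomputed [region_means()] result.
#' @return the scalar energy.
#' @export
cv_energy <- function(image, phi, params = cv_params(), stats = NULL) {
  if (!all(dim(image) == dim(phi))) stop_invalid("image and phi dimensions differ")
  if (is.null(stats)) stats <- region_means(image, phi)
  mu <- resolve_mu(params, image)
  p <- params$fit_exponent
  H <- heaviside_eps(phi, params$epsilon)
  Hx <- (shift_neumann(H, 0L, 1L) - shift_neumann(H, 0L, -1L)) / 2
  Hy <- (shift_neumann(H, 1L, 0L) - shift_neumann(H, -1L, 0L)) / 2
  len <- sum(sqrt(Hx^2 + Hy^2))
  area <- sum(H)
  inside <- phi > 0
  fit_out <- sum(abs(image[!inside] - stats$c1)^p)
  fit_in <- sum(abs(image[inside] - stats$c2)^p)
  mu * len + params$nu * area + params$lambda1 * fit_out + params$lambda2 * fit_in
}

# Mean-curvature of the phi iso-lines by central finite differences.
curvature <- function(phi) {
  px <- (shift_neumann(phi, 0L, 1L) - shift_neumann(phi, 0L, -1L)) / 2
  py <- (shift_neumann(phi, 1L, 0L) - shift_neumann(phi, -1L, 0L)) / 2
  pxx <- shift_neumann(phi, 0L, 1L) - 2 * phi + shift_neumann(phi, 0L, -1L)
  pyy <- shift_neumann(phi, 1L, 0L) - 2 * phi + shift_neumann(phi, -1L, 0L)
  pxy <- (shift_neumann(phi, 1L, 1L) - shift_neumann(phi, 1L, -1L) -
          shift_neumann(phi, -1L, 1L) + shift_neumann(phi, -1L, -1L)) / 4
  num <- pxx * py^2 - 2 * px * py * pxy + pyy * px^2
  den <- (px^2 + py^2)^1.5 + 1e-8
  num / den
}

# phi is clamped instead of periodically redistanced; the clamp bounds the
# field so the smoothed Dirac never fully switches off far from the contour.
PHI_CLAMP <- 50

#' One explicit gradient-descent step of the level-set evolution
#'
#' Updates `phi` by `dt * delta_eps(phi) * (mu * kappa - nu
#' + lambda1 |I - c1|^p - lambda2 |I - c2|^p)`: a pixel whose intensity is
#' close to the inside (foreground) estimate `c2` gains level-set value and
#' moves into the contour, and vice versa. Spatial derivatives use
#' replicated-edge boundaries; the output is clamped to `[-50, 50]`.
#'
#' @inheritParams cv_energy
#' @return the updated `phi` matrix.
#' @export
evolve_step <- function(image, phi, params = cv_params(), stats = NULL) {
  if (!all(dim(image) == dim(phi))) stop_invalid("image and phi dimensions differ")
  if (params$dt == 0) return(phi)
  if (is.null(stats)) stats <- region_means(image, phi)
  mu <- resolve_mu(params, image)
  p <- params$fit_exponent
  force <- mu * curvature(phi) - params$nu +
    params$lambda1 * abs(image - stats$c1)^p -
    params$lambda2 * abs(image - stats$c2)^p
  out <- phi + params$dt * dirac_eps(phi, params$epsilon) * force
  pmin(pmax(out, -PHI_CLAMP), PHI_CLAMP)
}

#' Segment a single-stoma image with the Chan-Vese model
#'
#' Seeds a circular contour at the ROI centre and evolves it for up to
#' `max_iters` iterations (default 300) or until the fraction of pixels that
#' changed sign in one iteration drops below `tol`. The returned mask is the
#' positive phase — the region grown from the centre seed; no assumption is
#' made about the pore being darker or brighter than its surroundings.
#'
#' @param image grayscale matrix (see [validate_gray_image()]).
#' @param params a [cv_params()] object.
#' @param center optional `c(row, col)` seed, 0-based; default grid centre.
#' @return an object of class `cv_segmentation`: a list with `mask` (logical
#'   matrix of the positive phase), `phi` (final level set), `trace` (a
#'   data.frame of per-iteration `iteration`, `energy`, `c1`, `c2`,
#'   `area_inside`; iteration 0 is the initial state), `iterations`, and
#'   `converged`.
#' @export
cv_segment <- function(image, params = cv_params(), center = NULL) {
  validate_gray_image(image)
  if (diff(range(image)) < 1e-8) {
    stop_stomapore("empty_segmentation",
      "image is constant: no two-phase structure to segment")
  }
  min_iters <- 10L  # convergence is only tested after the front has moved
  phi <- initialize_phi(dim(image), center = center, radius = params$init_radius)
  stats <- region_means(image, phi)
  trace <- vector("list", params$max_iters + 1L)
  trace[[1L]] <- data.frame(
    iteration = 0L, energy = cv_energy(image, phi, params, stats),
    c1 = stats$c1, c2 = stats$c2, area_inside = sum(phi > 0)
  )
  iterations <- 0L
  converged <- FALSE
  npix <- length(phi)
  for (i in seq_len(params$max_iters)) {
    phi_new <- evolve_step(image, phi, params, stats)
    flips <- sum((phi_new > 0) != (phi > 0)) / npix
    phi <- phi_new
    iterations <- i
    n_in <- sum(phi > 0)
    if (n_in == 0L || n_in == npix) {
      stop_stomapore("empty_segmentation",
        sprintf("level set collapsed to a single phase at iteration %d", i))
    }
    stats <- region_means(image, phi)
    trace[[i + 1L]] <- data.frame(
      iteration = i, energy = cv_energy(image, phi, params, stats),
      c1 = stats$c1, c2 = stats$c2, area_inside = n_in
    )
    if (i >= min_iters && flips < params$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(
    mask = phi > 0,
    phi = phi,
    trace = do.call(rbind, trace[seq_len(iterations + 1L)]),
    iterations = iterations,
    converged = converged
  ), class = "cv_segmentation")
}

#' @export
print.cv_segmentation <- function(x, ...) {
  cat(sprintf(
    "Chan-Vese segmentation: %dx%d grid, %d iterations (%s), %d px inside\n",
    nrow(x$mask), ncol(x$mask), x$iterations,
    if (x$converged) "converged" else "budget reached", sum(x$mask)
  ))
  e <- x$trace$energy
  cat(sprintf("  energy %.4g -> %.4g; c1 = %.2f, c2 = %.2f\n",
    e[1], e[length(e)], x$trace$c1[nrow(x$trace)], x$trace$c2[nrow(x$trace)]))
  invisible(x)
}
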