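# Synthetic single-stoma ROI generator with exact ground truth.
#
# The rendered world: an elliptical pore (known centre, semi-axes, angle)
# surrounded by a guard-cell ring, on a background carrying smooth
# low-frequency texture, with additive Gaussian noise; bright-field images
# additionally carry specular reflection blobs inside the pore. All
# stochasticity flows through the single per-spec seed.

#' Specification of a synthetic stoma image
#'
#' Default intensities by illumination mode: dark field renders a dark pore
#' (40) inside a bright guard ring (180) on a mid-dark background (90), with
#' noise sigma 6 and texture amplitude 8. Bright field emulates the
#' transmitted-light appearance of the comparison datasets: a dark pore (60)
#' between mid-gray guard cells (120) on a bright background (150), gentler
#' noise (sigma 4) and texture (5), plus saturated specular reflection blobs
#' inside the pore (default 3, Gaussian radius b/5, peak 255). The saturated
#' glints inflate both the image intensity range (hence the auto-scaled
#' smoothing weight) and the outside-mean estimate, which drags mid-gray
#' guard pixels into the pore phase and distorts the contour — the
#' over-segmentation that reflection removal corrects.
#'
#' @param shape `c(height, width)` in pixels (default 128 x 128).
#' @param a,b true semi-major / semi-minor axes of the pore, px.
#' @param theta true orientation, radians.
#' @param center true pore centre `c(row, col)`, 0-based; `NULL` = grid
#'   centre.
#' @param field `"dark"` or `"bright"`.
#' @param pore_intensity,guard_intensity,background_intensity base
#'   intensities in \[0, 255\]; `NULL` picks the per-field defaults above.
#' @param guard_ring_width guard-cell ring width in px (default 6).
#' @param noise_sigma additive Gaussian noise sd; `NULL` = field default.
#' @param texture_amplitude background texture amplitude; `NULL` = field
#'   default.
#' @param reflection_blobs number of specular blobs inside the pore
#'   (bright field only).
#' @param reflection_sigma Gaussian radius of each blob in px; `NULL` uses
#'   `max(1.2, b / 5)`.
#' @param seed integer seed driving all randomness of the render.
#' @return an object of class `stoma_spec`.
#' @export
stoma_spec <- function(shape = c(128L, 128L), a = 35, b = 17.5, theta = 0,
                       center = NULL, field = c("dark", "bright"),
                       pore_intensity = NULL, guard_intensity = NULL,
                       background_intensity = NULL, guard_ring_width = 6,
                       noise_sigma = NULL, texture_amplitude = NULL,
                       reflection_blobs = NULL, reflection_sigma = NULL,
                       seed = 1L) {
  field <- match.arg(field)
  defaults <- if (field == "dark") {
    list(pore = 40, guard = 180, background = 90, noise = 6, texture = 8, blobs = 0L)
  } else {
    list(pore = 60, guard = 120, background = 150, noise = 4, texture = 5, blobs = 3L)
  }
  if (is.null(pore_intensity)) pore_intensity <- defaults$pore
  if (is.null(guard_intensity)) guard_intensity <- defaults$guard
  if (is.null(background_intensity)) background_intensity <- defaults$background
  if (is.null(noise_sigma)) noise_sigma <- defaults$noise
  if (is.null(texture_amplitude)) texture_amplitude <- defaults$texture
  if (is.null(reflection_blobs)) reflection_blobs <- defaults$blobs
  if (is.null(center)) center <- floor(shape / 2)

  if (length(shape) != 2 || any(shape < 16)) stop_invalid("shape must be at least 16 x 16")
  if (!is.finite(a) || !is.finite(b) || b <= 0 || a < b) stop_invalid("need a >= b > 0")
  ints <- c(pore_intensity, guard_intensity, background_intensity)
  if (any(ints < 0 | ints > 255)) stop_invalid("intensities must lie in [0, 255]")
  if (noise_sigma < 0 || texture_amplitude < 0) stop_invalid("noise and texture must be >= 0")
  if (field == "dark" && pore_intensity >= guard_intensity) {
    stop_invalid("dark field requires the pore to be darker than the guard ring")
  }
  if (field == "dark" && reflection_blobs > 0) {
    stop_invalid("reflection blobs are a bright-field feature")
  }
  # pore (plus guard ring) must sit fully inside the grid with a 4 px margin
  ext <- a + guard_ring_width + 4
  if (center[1] - ext < -0.5 || center[1] + ext > shape[1] - 0.5 ||
      center[2] - ext < -0.5 || center[2] + ext > shape[2] - 0.5) {
    stop_invalid("pore (with guard ring and 4 px margin) does not fit in the grid")
  }
  structure(list(
    shape = as.integer(shape), a = a, b = b, theta = theta,
    center = as.numeric(center), field = field,
    pore_intensity = pore_intensity, guard_intensity = guard_intensity,
    background_intensity = background_intensity,
    guard_ring_width = guard_ring_width, noise_sigma = noise_sigma,
    texture_amplitude = texture_amplitude,
    reflection_blobs = as.integer(reflection_blobs),
    reflection_sigma = reflection_sigma, seed = as.integer(seed)
  ), class = "stoma_spec")
}

# Squared elliptical radius of every pixel centre w.r.t. an ellipse:
# u <= 1 inside. Returns a matrix over the full grid.
elliptical_radius2 <- function(shape, center, a, b, theta) {
  rows <- seq_len(shape[1]) - 1
  cols <- seq_len(shape[2]) - 1
  dy <- matrix(rows - center[1], shape[1], shape[2])
  dx <- matrix(cols - center[2], shape[1], shape[2], byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  u^2 + v^2
}

#' Render a synthetic stoma image with ground truth
#'
#' The pore mask is the centre-sampling rasterization of the true ellipse
#' (a pixel belongs to the pore iff its centre lies inside the ellipse), so
#' area oracles are well defined. Background texture is the mean of three
#' low-frequency sinusoids with seeded frequencies and phases. Bright-field
#' reflections are Gaussian-profile bright spots placed inside the pore at
#' equally spaced angles (seeded rotation), peaking at 255.
#'
#' @param spec a [stoma_spec()].
#' @return a list with `image` (grayscale matrix in \[0, 255\]) and `truth`
#'   (list with `mask`, `ellipse` (an [ellipse_params()]), `opening_degree`,
#'   `spec`).
#' @export
render_stoma <- function(spec) {
  if (!inherits(spec, "stoma_spec")) stop_invalid("spec must be a stoma_spec object")
  with_local_seed(spec$seed, {
    sh <- spec$shape
    u2 <- elliptical_radius2(sh, spec$center, spec$a, spec$b, spec$theta)
    pore <- u2 <= 1
    ring <- elliptical_radius2(
      sh, spec$center,
      spec$a + spec$guard_ring_width, spec$b + spec$guard_ring_width,
      spec$theta
    ) <= 1 & !pore

    img <- matrix(spec$background_intensity, sh[1], sh[2])
    if (spec$texture_amplitude > 0) {
      rows <- matrix(seq_len(sh[1]) - 1, sh[1], sh[2])
      cols <- matrix(seq_len(sh[2]) - 1, sh[1], sh[2], byrow = TRUE)
      tex <- 0
      for (k in 1:3) {
        fr <- stats::runif(1, 0.5, 2) / min(sh)
        fc <- stats::runif(1, 0.5, 2) / min(sh)
        ph <- stats::runif(1, 0, 2 * pi)
        tex <- tex + sin(2 * pi * (fr * rows + fc * cols) + ph)
      }
      img <- img + spec$texture_amplitude * tex / 3
    }
    img[ring] <- spec$guard_intensity
    img[pore] <- spec$pore_intensity

    if (spec$reflection_blobs > 0L) {
      k <- spec$reflection_blobs
      t0 <- stats::runif(1, 0, 2 * pi)
      sigma_b <- if (!is.null(spec$reflection_sigma)) spec$reflection_sigma
                 else max(1.2, spec$b / 5)
      ct <- cos(spec$theta); st <- sin(spec$theta)
      rows <- matrix(seq_len(sh[1]) - 1, sh[1], sh[2])
      cols <- matrix(seq_len(sh[2]) - 1, sh[1], sh[2], byrow = TRUE)
      for (j in seq_len(k)) {
        tj <- t0 + 2 * pi * (j - 1) / k
        # blob centre at elliptical radius 0.5, inside the pore
        ex <- 0.5 * spec$a * cos(tj)
        ey <- 0.5 * spec$b * sin(tj)
        bc_col <- spec$center[2] + ex * ct - ey * st
        bc_row <- spec$center[1] + ex * st + ey * ct
        d2 <- (rows - bc_row)^2 + (cols - bc_col)^2
        bump <- (255 - spec$pore_intensity) * exp(-d2 / (2 * sigma_b^2))
        img <- img + bump * pore  # reflections live inside the pore
      }
    }

    if (spec$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma), sh[1], sh[2])
    }
    img <- pmin(pmax(img, 0), 255)

    list(
      image = img,
      truth = list(
        mask = pore,
        ellipse = ellipse_params(spec$center, spec$a, spec$b, spec$theta),
        opening_degree = spec$b / spec$a,
        spec = spec
      )
    )
  })
}

# Opening-degree strata mirroring the reporting bins used for real stomata:
# (0.4, 1], (0.3, 0.4], (0.2, 0.3], (0.1, 0.2].
OD_BINS <- cbind(lo = c(0.4, 0.3, 0.2, 0.1), hi = c(1.0, 0.4, 0.3, 0.2))

#' Generate a seeded synthetic stoma dataset
#'
#' Draws `n` specifications from parameter ranges with a single explicit
#' seed and renders each. Opening degrees are stratified round-robin over
#' the bins (0.1, 0.2], (0.2, 0.3], (0.3, 0.4], (0.4, 1] intersected with
#' `od` range, so every bin the range covers receives ~n/4 samples.
#'
#' @param n number of stomata, >= 1.
#' @param ranges list of ranges overriding the defaults: `a = c(15, 45)`,
#'   `od = c(0.1, 0.9)`, `theta = c(0, pi)`, plus scalars `shape`,
#'   `field`, `noise_sigma`, `texture_amplitude`, `reflection_blobs`,
#'   `guard_ring_width`, `center_jitter` (default 3 px).
#' @param seed integer seed.
#' @return a list of `n` elements, each a `render_stoma()` result (fields
#'   `image`, `truth`).
#' @export
generate_dataset <- function(n, ranges = list(), seed = 1L) {
  if (!is.numeric(n) || n < 1) stop_invalid("n must be >= 1")
  n <- as.integer(n)
  def <- list(
    a = c(15, 45), od = c(0.1, 0.9), theta = c(0, pi),
    shape = c(128L, 128L), field = "dark",
    noise_sigma = NULL, texture_amplitude = NULL, reflection_blobs = NULL,
    reflection_sigma = NULL, guard_ring_width = 6, center_jitter = 3
  )
  def[names(ranges)] <- ranges
  shape <- def$shape
  a_max_feasible <- min(shape) / 2 - def$guard_ring_width - 4 - def$center_jitter - 1
  a_range <- c(def$a[1], min(def$a[2], a_max_feasible))
  if (a_range[1] > a_range[2]) {
    stop_invalid("pore size range is infeasible for the requested grid")
  }
  bins_ok <- which(OD_BINS[, "hi"] > def$od[1] & OD_BINS[, "lo"] < def$od[2])
  with_local_seed(seed, {
    spec_seeds <- sample.int(.Machine$integer.max, n)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (length(bins_ok) > 0L) {
        b_i <- bins_ok[((i - 1L) %% length(bins_ok)) + 1L]
        lo <- max(OD_BINS[b_i, "lo"], def$od[1])
        hi <- min(OD_BINS[b_i, "hi"], def$od[2])
        od <- stats::runif(1, lo, hi)
      } else {
        od <- stats::runif(1, def$od[1], def$od[2])
      }
      a <- stats::runif(1, a_range[1], a_range[2])
      theta <- stats::runif(1, def$theta[1], def$theta[2])
      jit <- stats::runif(2, -def$center_jitter, def$center_jitter)
      spec <- stoma_spec(
        shape = shape, a = a, b = od * a, theta = theta,
        center = floor(shape / 2) + jit, field = def$field,
        guard_ring_width = def$guard_ring_width,
        noise_sigma = def$noise_sigma,
        texture_amplitude = def$texture_amplitude,
        reflection_blobs = def$reflection_blobs,
        reflection_sigma = def$reflection_sigma,
        seed = spec_seeds[i]
      )
      out[[i]] <- render_stoma(spec)
    }
    out
  })
}
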