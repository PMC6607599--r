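# Pore morphometry from the fitted ellipse, in pixels and micrometres.

#' Pixel scale
#'
#' Pixel-to-micrometre scale of the microscope setup. The default, 4.8
#' pixels per micrometre, corresponds to a 1000x magnification acquisition.
#'
#' @param pixels_per_um pixels per micrometre, > 0.
#' @return an object of class `scale_spec`.
#' @export
scale_spec <- function(pixels_per_um = 4.8) {
  if (!is.finite(pixels_per_um) || pixels_per_um <= 0) {
    stop_invalid("pixels_per_um must be > 0")
  }
  structure(list(pixels_per_um = pixels_per_um), class = "scale_spec")
}

#' Convert pixel lengths to micrometres
#'
#' @param length_px length(s) in pixels.
#' @param scale a [scale_spec()].
#' @return length(s) in micrometres.
#' @export
pixels_to_micrometers <- function(length_px, scale = scale_spec()) {
  if (!inherits(scale, "scale_spec")) scale <- scale_spec(scale)
  length_px / scale$pixels_per_um
}

#' Convert micrometre lengths to pixels
#'
#' @param length_um length(s) in micrometres.
#' @inheritParams pixels_to_micrometers
#' @return length(s) in pixels.
#' @export
micrometers_to_pixels <- function(length_um, scale = scale_spec()) {
  if (!inherits(scale, "scale_spec")) scale <- scale_spec(scale)
  length_um * scale$pixels_per_um
}

#' Pore morphology metrics from a fitted ellipse
#'
#' Computes, from the semi-axes a >= b of the fitted pore ellipse:
#' area `A = pi * a * b`, eccentricity `e = sqrt(1 - (b/a)^2)` and opening
#' degree `Od = b / a` (so `e^2 + Od^2 = 1` identically). Full axes `2a`,
#' `2b` are reported in pixels and micrometres; areas in px^2 and um^2.
#' A pore whose minor axis `2b` is below `min_minor_axis_px` (default 4 px,
#' about 0.83 um at 4.8 px/um) is flagged `closed_or_too_small`: below that
#' aperture the centre seed usually misses the pore and the stoma is
#' physiologically closed.
#'
#' @param ellipse an [ellipse_params()] object.
#' @param scale a [scale_spec()].
#' @param min_minor_axis_px minimum trustworthy minor-axis length in px.
#' @return an object of class `pore_measurement`: list with `a_px`, `b_px`,
#'   `major_axis_px`, `minor_axis_px`, `major_axis_um`, `minor_axis_um`,
#'   `area_px2`, `area_um2`, `eccentricity`, `opening_degree`, `status`
#'   (`"ok"` or `"closed_or_too_small"`).
#' @export
pore_metrics <- function(ellipse, scale = scale_spec(), min_minor_axis_px = 4) {
  if (!inherits(ellipse, "ellipse_params")) stop_invalid("ellipse must be an ellipse_params object")
  a <- ellipse$a; b <- ellipse$b
  if (!is.finite(b) || b <= 0) stop_invalid("semi-minor axis must be > 0")
  ppu <- scale$pixels_per_um
  area_px2 <- pi * a * b
  od <- b / a
  ecc <- sqrt(1 - od^2)
  status <- if (2 * b < min_minor_axis_px) "closed_or_too_small" else "ok"
  structure(list(
    a_px = a, b_px = b,
    major_axis_px = 2 * a, minor_axis_px = 2 * b,
    major_axis_um = 2 * a / ppu, minor_axis_um = 2 * b / ppu,
    area_px2 = area_px2, area_um2 = area_px2 / ppu^2,
    eccentricity = ecc, opening_degree = od,
    status = status
  ), class = "pore_measurement")
}

#' @export
print.pore_measurement <- function(x, ...) {
  cat(sprintf("Pore measurement [%s]\n", x$status))
  cat(sprintf("  major axis: %.2f px (%.2f um)\n", x$major_axis_px, x$major_axis_um))
  cat(sprintf("  minor axis: %.2f px (%.2f um)\n", x$minor_axis_px, x$minor_axis_um))
  cat(sprintf("  area: %.1f px^2 (%.2f um^2)\n", x$area_px2, x$area_um2))
  cat(sprintf("  eccentricity: %.4f, opening degree: %.4f\n",
              x$eccentricity, x$opening_degree))
  invisible(x)
}
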