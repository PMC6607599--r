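# End-to-end per-stoma pipeline and batch driver: grayscale conversion,
# optional reflection removal (bright field), Chan-Vese segmentation,
# central-region selection, hole filling, solidity analysis with
# conditional morphological disconnection, boundary extraction, ellipse
# fitting (moments fallback) and morphometry.

#' Pipeline configuration
#'
#' @param cv a [cv_params()] object.
#' @param solidity_threshold independence threshold (default 0.85).
#' @param se_radius starting disconnection disk radius in px (default 2).
#' @param max_rounds maximum disconnection rounds (default 3).
#' @param scale a [scale_spec()].
#' @param field_mode `"auto"`, `"dark"` or `"bright"`. Bright-field images
#'   get specular-reflection removal before segmentation; `"auto"` applies
#'   it when > 1\% of the pixels in the central neighbourhood exceed
#'   `mean + 2 sd` of the image.
#' @param reflection_k std-dev multiplier of the reflection threshold
#'   (default 2).
#' @param min_minor_axis_px minimum trustworthy minor axis (default 4 px).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cv = cv_params(), solidity_threshold = 0.85,
                            se_radius = 2, max_rounds = 3L,
                            scale = scale_spec(),
                            field_mode = c("auto", "dark", "bright"),
                            reflection_k = 2, min_minor_axis_px = 4) {
  field_mode <- match.arg(field_mode)
  if (solidity_threshold <= 0 || solidity_threshold > 1) {
    stop_invalid("solidity_threshold must lie in (0, 1]")
  }
  if (min_minor_axis_px < 1) stop_invalid("min_minor_axis_px must be >= 1")
  structure(list(
    cv = cv, solidity_threshold = solidity_threshold,
    se_radius = se_radius, max_rounds = as.integer(max_rounds),
    scale = scale, field_mode = field_mode, reflection_k = reflection_k,
    min_minor_axis_px = min_minor_axis_px
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `cv` and `scale`
#' keys are nested maps passed to [cv_params()] and [scale_spec()].
#'
#' @param path YAML file path.
#' @return a [pipeline_config()] object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cv)) args$cv <- do.call(cv_params, y$cv)
  if (!is.null(y$scale)) args$scale <- do.call(scale_spec, y$scale)
  for (k in c("solidity_threshold", "se_radius", "max_rounds", "field_mode",
              "reflection_k", "min_minor_axis_px")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

#' Convert an image to grayscale
#'
#' Three-channel inputs are reduced with the luma weights
#' 0.299 R + 0.587 G + 0.114 B; single-channel inputs pass through.
#'
#' @param image numeric matrix or height x width x \{1, 3\} array, \[0, 255\].
#' @return numeric matrix in \[0, 255\].
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  d <- dim(image)
  if (length(d) == 3 && d[3] == 1) return(image[, , 1])
  if (length(d) == 3 && d[3] == 3) {
    return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  stop_invalid("image must be a matrix or an array with 1 or 3 channels")
}

#' Remove specular reflections
#'
#' Pixels strictly brighter than `mean + k * sd` of the image are replaced
#' by the global mean intensity of the original image; all other pixels are
#' unchanged. This suppresses the bright specular spots that bright-field
#' illumination produces inside the pore, which otherwise carve notches in
#' the segmented region.
#'
#' @param image grayscale matrix.
#' @param k std-dev multiplier (default 2).
#' @return matrix of the same dimensions.
#' @export
remove_reflections <- function(image, k = 2) {
  m <- mean(image)
  s <- stats::sd(image)
  out <- image
  out[image > m + k * s] <- m
  out
}

# Heuristic bright-field detector: fraction of pixels above mean + 2 sd
# within the central neighbourhood (disk of radius min(dim)/4 around the
# seed) exceeding 1% signals in-pore reflections.
detect_bright_field <- function(image, center = NULL, k = 2) {
  if (is.null(center)) center <- floor(dim(image) / 2)
  radius <- min(dim(image)) / 4
  rows <- seq_len(nrow(image)) - 1
  cols <- seq_len(ncol(image)) - 1
  d2 <- outer((rows - center[1])^2, (cols - center[2])^2, `+`)
  neigh <- d2 <= radius^2
  thr <- mean(image) + k * stats::sd(image)
  mean(image[neigh] > thr) > 0.01
}

#' Measure one stoma ROI
#'
#' Runs the full pipeline on a single cropped stoma image: grayscale,
#' reflection removal (bright field), Chan-Vese segmentation seeded at the
#' ROI centre, central-component selection, hole filling, solidity
#' analysis, morphological disconnection when the region is not
#' independent, boundary extraction, direct least-squares ellipse fit
#' (moment-based fallback) and pore morphometry. Stage failures never
#' raise: they are encoded in the result's `status`/`failed_stage`.
#'
#' @param roi grayscale matrix or RGB array, at least 16 x 16.
#' @param config a [pipeline_config()].
#' @return an object of class `stoma_result`: list with `status` (`"ok"`,
#'   `"closed_or_too_small"` or `"failed"`), `failed_stage` (`NA` unless
#'   failed), `measurement` ([pore_metrics()] result or `NULL`), `shape`
#'   ([region_solidity()] report or `NULL`), `ellipse`, `mask`, and
#'   `diagnostics` (iterations, convergence, initial/final energy,
#'   disconnection rounds, whether reflections were removed).
#' @export
measure_stoma <- function(roi, config = pipeline_config()) {
  res <- structure(list(
    status = "failed", failed_stage = NA_character_,
    measurement = NULL, shape = NULL, ellipse = NULL, mask = NULL,
    diagnostics = list(iterations = NA_integer_, converged = NA,
                       energy_initial = NA_real_, energy_final = NA_real_,
                       rounds = 0L, reflection_removed = FALSE)
  ), class = "stoma_result")
  fail <- function(stage, e) {
    res$status <<- "failed"
    res$failed_stage <<- stage
    res$diagnostics$error <<- conditionMessage(e)
    res
  }

  gray <- tryCatch(to_grayscale(roi), error = function(e) e)
  if (inherits(gray, "error")) return(fail("grayscale", gray))
  ok <- tryCatch(validate_gray_image(gray), error = function(e) e)
  if (inherits(ok, "error")) return(fail("validate", ok))

  bright <- switch(config$field_mode,
    dark = FALSE,
    bright = TRUE,
    auto = detect_bright_field(gray, k = config$reflection_k)
  )
  if (bright) {
    gray <- remove_reflections(gray, config$reflection_k)
    res$diagnostics$reflection_removed <- TRUE
  }

  seg <- tryCatch(cv_segment(gray, config$cv), error = function(e) e)
  if (inherits(seg, "error")) return(fail("segmentation", seg))
  res$diagnostics$iterations <- seg$iterations
  res$diagnostics$converged <- seg$converged
  res$diagnostics$energy_initial <- seg$trace$energy[1]
  res$diagnostics$energy_final <- seg$trace$energy[nrow(seg$trace)]

  region <- tryCatch({
    m <- select_central_region(seg$mask)
    raw_area <- sum(m)
    f <- fill_holes(m)
    attr(f, "fill_ratio") <- sum(f) / raw_area
    ctr <- floor(dim(f) / 2) + 1L
    attr(f, "seed_in_hole") <- f[ctr[1], ctr[2]] && !m[ctr[1], ctr[2]]
    f
  }, error = function(e) e)
  if (inherits(region, "error")) return(fail("region-selection", region))
  fill_ratio <- attr(region, "fill_ratio")
  seed_in_hole <- attr(region, "seed_in_hole")
  attr(region, "fill_ratio") <- NULL
  attr(region, "seed_in_hole") <- NULL
  # Guard-ring capture: when the aperture is only a few pixels wide the
  # centre seed region is dominated by the guard cells and the contour
  # wraps around the bright ring instead of the pore. The tell-tales are a
  # filled area far exceeding the raw area (annulus) or the seed centre
  # itself being classified background and recovered only by hole filling
  # (the pore is the hole). Either way the ellipse would describe the guard
  # cells, not the pore, so the stoma is reported as closed.
  if (fill_ratio > 1.25 || seed_in_hole) {
    res$diagnostics$annular <- TRUE
    res$mask <- region
    res$status <- "closed_or_too_small"
    res$failed_stage <- NA_character_
    return(res)
  }

  shape <- tryCatch(region_solidity(region, config$solidity_threshold),
                    error = function(e) e)
  if (inherits(shape, "error")) return(fail("shape-analysis", shape))
  if (!shape$independent) {
    region2 <- tryCatch(
      disconnect_region(region, se_radius = config$se_radius,
                        max_rounds = config$max_rounds,
                        threshold = config$solidity_threshold),
      error = function(e) e
    )
    if (inherits(region2, "error")) return(fail("disconnect", region2))
    res$diagnostics$rounds <- attr(region2, "rounds")
    shape <- attr(region2, "shape")
    attr(region2, "rounds") <- NULL
    attr(region2, "shape") <- NULL
    region <- fill_holes(region2)
  }
  res$mask <- region
  res$shape <- shape

  ell <- tryCatch({
    pts <- extract_boundary(region)
    tryCatch(fit_ellipse(pts), stomapore_fit_failed = function(e) {
      ellipse_from_moments(region)
    })
  }, error = function(e) e)
  if (inherits(ell, "error")) return(fail("ellipse-fit", ell))
  res$ellipse <- ell

  meas <- tryCatch(pore_metrics(ell, config$scale, config$min_minor_axis_px),
                   error = function(e) e)
  if (inherits(meas, "error")) return(fail("measurement", meas))
  res$measurement <- meas
  res$status <- meas$status
  res
}

#' @export
print.stoma_result <- function(x, ...) {
  cat(sprintf("Stoma result [%s]%s\n", x$status,
              if (!is.na(x$failed_stage)) sprintf(" at stage '%s'", x$failed_stage) else ""))
  if (!is.null(x$measurement)) print(x$measurement)
  if (!is.null(x$shape)) {
    cat(sprintf("  solidity: %.3f (%s)\n", x$shape$solidity,
                if (x$shape$independent) "independent" else "non-independent"))
  }
  invisible(x)
}

result_row <- function(id, image, res) {
  m <- res$measurement
  data.frame(
    id = id, image = image, status = res$status,
    failed_stage = if (is.na(res$failed_stage)) "" else res$failed_stage,
    major_px = if (is.null(m)) NA_real_ else m$major_axis_px,
    minor_px = if (is.null(m)) NA_real_ else m$minor_axis_px,
    major_um = if (is.null(m)) NA_real_ else m$major_axis_um,
    minor_um = if (is.null(m)) NA_real_ else m$minor_axis_um,
    area_um2 = if (is.null(m)) NA_real_ else m$area_um2,
    eccentricity = if (is.null(m)) NA_real_ else m$eccentricity,
    opening_degree = if (is.null(m)) NA_real_ else m$opening_degree,
    solidity = if (is.null(res$shape)) NA_real_ else res$shape$solidity,
    iterations_used = res$diagnostics$iterations,
    stringsAsFactors = FALSE
  )
}

#' Run the pipeline over a batch of images
#'
#' Each input image is either processed whole (one ROI per image) or
#' cropped into ROIs by a bounding-box sidecar (see [read_boxes()]; boxes
#' are 0-based half-open). Unreadable files and out-of-bounds boxes are
#' recorded as failed rows and the run continues. The pipeline itself is
#' deterministic: identical inputs and configuration give byte-identical
#' CSV output.
#'
#' @param inputs character vector of image paths, or a list of in-memory
#'   images (matrices/arrays; names become ids).
#' @param config a [pipeline_config()].
#' @param boxes optional sidecar path or data.frame (see [read_boxes()]).
#' @param out_csv optional path: results are written as CSV.
#' @param save_masks optional directory: per-ROI masks written as
#'   `<id>_mask.png`.
#' @param quiet suppress per-ROI progress messages on stderr.
#' @return a data.frame with one row per ROI: `id, image, status,
#'   failed_stage, major_px, minor_px, major_um, minor_um, area_um2,
#'   eccentricity, opening_degree, solidity, iterations_used`.
#' @export
run_batch <- function(inputs, config = pipeline_config(), boxes = NULL,
                      out_csv = NULL, save_masks = NULL, quiet = TRUE) {
  if (!is.null(boxes) && !is.data.frame(boxes)) boxes <- read_boxes(boxes)
  rois <- list()   # list of (id, image_name, roi or error-string)
  add <- function(id, image, roi) rois[[length(rois) + 1L]] <<- list(id = id, image = image, roi = roi)

  if (is.list(inputs) && !is.character(inputs)) {
    ids <- names(inputs)
    if (is.null(ids)) ids <- sprintf("roi_%03d", seq_along(inputs))
    for (i in seq_along(inputs)) add(ids[i], ids[i], inputs[[i]])
  } else {
    for (path in inputs) {
      name <- basename(path)
      img <- tryCatch(read_image(path), error = function(e) e)
      if (inherits(img, "error")) {
        add(name, name, "unreadable")
        next
      }
      bx <- if (is.null(boxes)) NULL else boxes[boxes$image == name, , drop = FALSE]
      if (is.null(bx) || nrow(bx) == 0L) {
        add(name, name, img)
      } else {
        d <- dim(img)
        for (j in seq_len(nrow(bx))) {
          b <- bx[j, ]
          id <- sprintf("%s#%s", name, b$id)
          if (b$row0 < 0 || b$col0 < 0 || b$row1 > d[1] || b$col1 > d[2] ||
              b$row1 <= b$row0 || b$col1 <= b$col0) {
            add(id, name, "bad-box")
          } else if (length(d) == 3) {
            add(id, name, img[(b$row0 + 1):b$row1, (b$col0 + 1):b$col1, , drop = FALSE])
          } else {
            add(id, name, img[(b$row0 + 1):b$row1, (b$col0 + 1):b$col1, drop = FALSE])
          }
        }
      }
    }
  }

  rows <- vector("list", length(rois))
  for (i in seq_along(rois)) {
    entry <- rois[[i]]
    t0 <- proc.time()[["elapsed"]]
    if (is.character(entry$roi)) {
      res <- structure(list(
        status = "failed", failed_stage = entry$roi, measurement = NULL,
        shape = NULL, ellipse = NULL, mask = NULL,
        diagnostics = list(iterations = NA_integer_)
      ), class = "stoma_result")
    } else {
      res <- measure_stoma(entry$roi, config)
      if (!is.null(save_masks) && !is.null(res$mask)) {
        dir.create(save_masks, showWarnings = FALSE, recursive = TRUE)
        write_image(res$mask, file.path(save_masks, paste0(gsub("[^A-Za-z0-9_.-]", "_", entry$id), "_mask.png")))
      }
    }
    if (!quiet) {
      message(sprintf("[%s] %s (%.2fs)%s", entry$id, res$status,
                      proc.time()[["elapsed"]] - t0,
                      if (!is.na(res$failed_stage)) paste0(" stage=", res$failed_stage) else ""))
    }
    rows[[i]] <- result_row(entry$id, entry$image, res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) {
    utils::write.csv(out, out_csv, row.names = FALSE)
  }
  out
}
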