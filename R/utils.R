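# Grid helpers shared by the level-set solver and the morphology code.
# Convention everywhere: (row, col), 0-based, pixel centres at integer
# coordinates; matrices are indexed [row, col] 1-based as usual in R.

#' Validate a grayscale image
#'
#' Checks that `image` is a finite numeric matrix with intensities in
#' \[0, 255\] and both dimensions at least 16 pixels (smaller crops carry too
#' little context for the level-set contour to be meaningful).
#'
#' @param image numeric matrix.
#' @param min_dim minimum number of rows and columns (default 16).
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_gray_image <- function(image, min_dim = 16L) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_invalid("image must be a numeric matrix")
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop_invalid(sprintf("image must be at least %dx%d pixels", min_dim, min_dim))
  }
  if (!all(is.finite(image))) stop_invalid("image contains non-finite intensities")
  if (min(image) < 0 || max(image) > 255) {
    stop_invalid("intensities must lie in [0, 255]")
  }
  invisible(image)
}

# Shift a matrix by (dr, dc) with replicated-edge (Neumann) boundaries:
# out[i, j] = m[clamp(i + dr), clamp(j + dc)].
shift_neumann <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Shift with constant fill outside the grid (used by morphology / labeling).
shift_pad <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L - dr):min(nr, nr - dr)
  cs <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(rs) > 0 && length(cs) > 0) out[rs, cs] <- m[rs + dr, cs + dc, drop = FALSE]
  out
}

# Run code with a private RNG stream: seeds, evaluates, restores .Random.seed.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Offsets (dr, dc) of a digital disk structuring element of radius r.
disk_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radius^2 + 1e-9, , drop = FALSE]
}
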