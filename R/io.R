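# Image and sidecar input/output. PNG via the png package; ASCII PGM/PPM
# (P2/P3) and CSV matrices are parsed directly so fixtures stay plain text.
# Images are represented in [0, 255] regardless of on-disk encoding.

#' Read an image file
#'
#' Supports PNG (`.png`), ASCII portable graymap/pixmap (`.pgm`/`.ppm`,
#' magic P2/P3) and CSV matrices (`.csv`). Grayscale files give a matrix;
#' RGB files give a height x width x 3 array. Intensities are rescaled to
#' \[0, 255\].
#'
#' @param path file path.
#' @return numeric matrix or 3-d array in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3 && dim(img)[3] >= 3) img <- img[, , 1:3, drop = FALSE]
    if (length(dim(img)) == 3 && dim(img)[3] == 1) img <- img[, , 1]
    return(img * 255)
  }
  if (ext %in% c("pgm", "ppm")) return(read_pnm_ascii(path))
  if (ext %in% c("csv", "txt")) {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "double"
    return(m)
  }
  stop_invalid(sprintf("unsupported image format: .%s", ext))
}

read_pnm_ascii <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)
  tok <- scan(text = paste(txt, collapse = " "), what = character(), quiet = TRUE)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3")) stop_invalid("only ASCII PGM (P2) / PPM (P3) supported")
  vals <- as.numeric(tok[-1])
  w <- vals[1]; h <- vals[2]; maxv <- vals[3]
  px <- vals[-(1:3)] * (255 / maxv)
  if (magic == "P2") {
    if (length(px) != w * h) stop_invalid("corrupt PGM: pixel count mismatch")
    matrix(px, nrow = h, ncol = w, byrow = TRUE)
  } else {
    if (length(px) != 3 * w * h) stop_invalid("corrupt PPM: pixel count mismatch")
    arr <- array(0, c(h, w, 3))
    for (ch in 1:3) {
      arr[, , ch] <- matrix(px[seq(ch, length(px), by = 3)], h, w, byrow = TRUE)
    }
    arr
  }
}

#' Write an image file
#'
#' PNG for `.png` paths (via the png package), ASCII PGM (P2) for `.pgm`.
#' Logical matrices (masks) are written as 0/255.
#'
#' @param image numeric matrix in \[0, 255\] or logical mask.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (is.logical(image)) {
    image <- matrix(as.numeric(image) * 255, nrow(image), ncol(image))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
    apply(round(image), 1, function(r) writeLines(paste(r, collapse = " "), con))
  } else {
    stop_invalid(sprintf("unsupported output format: .%s", ext))
  }
  invisible(path)
}

#' Read a bounding-box sidecar
#'
#' CSV with columns `image, row0, row1, col0, col1` (optionally `id`) or a
#' JSON array of objects with those fields. Boxes are 0-based half-open:
#' rows `[row0, row1)`, columns `[col0, col1)`.
#'
#' @param path sidecar path (`.csv` or `.json`).
#' @return data.frame with columns `id, image, row0, row1, col0, col1`.
#' @export
read_boxes <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("image", "row0", "row1", "col0", "col1")
  if (!all(need %in% names(df))) {
    stop_invalid(sprintf("box sidecar must have columns: %s", paste(need, collapse = ", ")))
  }
  if (is.null(df$id)) df$id <- seq_len(nrow(df))
  df[, c("id", need)]
}
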