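#' RGB micrograph images
#'
#' Images are stored as H-by-W-by-3 integer arrays with channel values in
#' 0..255 (class `rgb_image`). Greyscale input is promoted to three equal
#' channels. Pixel `[row, col]` has its center at geometry coordinates
#' `x = col - 0.5`, `y = row - 0.5` (origin at the top-left image corner).
#'
#' @param pixels H-by-W-by-3 array in 0..255, or an H-by-W matrix (promoted),
#'   or an array/matrix in `[0, 1]` (scaled to 0..255 when its maximum is
#'   <= 1 and it is not integer-valued above 1).
#' @return An `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), c(dim(pixels), 3))
  if (length(dim(pixels)) == 3L && dim(pixels)[3] == 4L) {
    pixels <- pixels[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    lq_abort("lq_argument_error", "pixels must be H x W x 3 (or H x W greyscale)")
  }
  if (max(pixels) <= 1 && min(pixels) >= 0 && !all(pixels == round(pixels))) {
    pixels <- pixels * 255
  } else if (max(pixels) <= 1 && min(pixels) >= 0) {
    # 0/1-valued data: treat as normalized intensities
    pixels <- pixels * 255
  }
  pixels <- round(pixels)
  if (min(pixels) < 0 || max(pixels) > 255) {
    lq_abort("lq_argument_error", "channel values outside 0..255")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px\n", d[1], d[2]))
  invisible(x)
}

#' Read and write micrograph images
#'
#' Thin wrappers over the png and tiff readers; the format is chosen by file
#' extension. Everything is normalized to an 8-bit [rgb_image()].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return `read_image()` returns an [rgb_image()]; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    lq_abort("lq_argument_error", sprintf("unsupported image format: .%s", ext))
  )
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3), c(dim(raw), 3))
  rgb_image(round(raw[, , 1:3, drop = FALSE] * 255))
}

#' @rdname read_image
#' @param image an [rgb_image()].
#' @export
write_image <- function(image, path) {
  arr <- unclass(image) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path),
    lq_abort("lq_argument_error", sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}

#' Invert image colors
#'
#' Maps every channel value v to 255 - v, so that dark stain (high transcript
#' signal) becomes high intensity before measurement.
#'
#' @param image an [rgb_image()].
#' @return The inverted `rgb_image`.
#' @export
invert_image <- function(image) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  out <- 255L - unclass(image)
  structure(out, class = "rgb_image")
}

# Vectorized even-odd point-in-polygon test. px/py are point coordinates,
# vx/vy the polygon vertices (closed implicitly). Returns logical vector.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    crosses <- ((y2 > py) != (y1 > py))
    if (any(crosses)) {
      xint <- (x1 - x2) * (py - y2) / (y1 - y2) + x2
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
    j <- i
  }
  inside
}
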