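#' Construct a modality image
#'
#' A modality image is a 2-D numeric matrix of fluorescence intensities
#' (arbitrary units) carrying the physical pixel pitch and a modality tag.
#' `NA` pixels are the sentinel for "outside the acquired frame" (they appear
#' after resampling one modality into the other's frame) and are excluded
#' from every downstream statistic.
#'
#' Coordinates throughout the package are `(row, col)`, 1-based, with pixel
#' centers at integer coordinates.
#'
#' @param data numeric matrix of intensities.
#' @param pixel_pitch physical size of one pixel in mm/pixel.
#' @param modality free-text tag, e.g. `"NIR"` or `"SWIR"`.
#' @return a `modality_image` object (a matrix with attributes).
#' @export
modality_image <- function(data, pixel_pitch = 1, modality = "unknown") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("image data must be numeric")
  if (!is.numeric(pixel_pitch) || length(pixel_pitch) != 1L || pixel_pitch <= 0)
    stop("pixel_pitch must be a single positive number (mm/pixel)")
  structure(data,
            pixel_pitch = pixel_pitch,
            modality = as.character(modality),
            class = c("modality_image", "matrix", "array"))
}

#' @export
print.modality_image <- function(x, ...) {
  cat(sprintf("<modality_image> %s, %d x %d px, pitch %g mm/px, %d NA px\n",
              attr(x, "modality"), nrow(x), ncol(x),
              attr(x, "pixel_pitch"), sum(is.na(x))))
  invisible(x)
}

# Plain numeric matrix view (drops class, keeps dims).
img_data <- function(image) {
  m <- unclass(image)
  attr(m, "pixel_pitch") <- NULL
  attr(m, "modality") <- NULL
  m
}

img_pitch <- function(image, default = 1) {
  p <- attr(image, "pixel_pitch")
  if (is.null(p)) default else p
}

#' Read / write single-channel float TIFF images
#'
#' On-disk convention: single-channel 32-bit float TIFF with intensities in
#' `[0, 1]` (writing clips to that range, like a physical sensor; clipping to
#' disk is an explicit step and the in-memory floats remain the ground truth).
#'
#' @param path file path.
#' @param pixel_pitch,modality metadata attached to the returned image.
#' @return `read_image_tiff` returns a [modality_image()].
#' @export
read_image_tiff <- function(path, pixel_pitch = 1, modality = "unknown") {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  modality_image(m, pixel_pitch = pixel_pitch, modality = modality)
}

#' @param image a [modality_image()] or numeric matrix.
#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  m <- img_data(image)
  if (anyNA(m)) stop("cannot write an image containing NA (sentinel) pixels")
  m <- pmin(pmax(m, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read / write binary masks as 8-bit PNG (0/255)
#'
#' @param path file path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m >= 0.5
}

#' @param mask logical (or 0/1 numeric) matrix.
#' @rdname read_mask_png
#' @export
write_mask_png <- function(mask, path) {
  m <- (as.matrix(mask) != 0) * 1.0
  png::writePNG(m, path)
  invisible(path)
}

# Separable Gaussian blur with replicate (edge-clamp) padding.
# Kernel truncated at 4 sigma; sigma = 0 returns the input unchanged.
blur_gaussian <- function(m, sigma) {
  if (sigma < 0) stop("blur sigma must be >= 0")
  if (sigma == 0) return(m)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  m <- conv_dim1(m, w, r)
  t(conv_dim1(t(m), w, r))
}

conv_dim1 <- function(m, w, r) {
  n <- nrow(m)
  pad <- rbind(m[rep(1L, r), , drop = FALSE], m, m[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * pad[k:(k + n - 1L), , drop = FALSE]
  }
  out
}
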