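#' Single-channel image with a physical pixel size
#'
#' An `image_plane` is a numeric matrix of intensities in `[0, 1]`
#' (rows = y, columns = x) carrying the physical pixel size in nm/pixel as
#' an attribute. Most functions in the package accept either an
#' `image_plane` or a plain matrix.
#'
#' @param data numeric matrix of intensities in `[0, 1]`.
#' @param pixel_size_nm physical size of one pixel in nanometres (default
#'   1.11, the 43k-magnification sampling typical of the intended data).
#' @return an `image_plane` object.
#' @export
image_plane <- function(data, pixel_size_nm = 1.11) {
  stopifnot(is.matrix(data), is.numeric(data), pixel_size_nm > 0)
  structure(data, pixel_size_nm = pixel_size_nm, class = c("image_plane", "matrix"))
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.3g nm/pixel, range [%.3f, %.3f]\n",
              nrow(x), ncol(x), pixel_size_nm(x), min(x), max(x)))
  invisible(x)
}

#' Pixel size of an image
#' @param x an `image_plane` (plain matrices fall back to `default`).
#' @param default value returned when `x` carries no pixel size.
#' @return pixel size in nm/pixel.
#' @export
pixel_size_nm <- function(x, default = 1.11) {
  ps <- attr(x, "pixel_size_nm")
  if (is.null(ps)) default else ps
}

as_plain_matrix <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' Read a single-channel image (TIFF or PNG)
#'
#' Multi-channel files are collapsed to their first channel. Values are
#' returned in `[0, 1]`.
#'
#' @param path file path; format chosen by extension (`.tif`/`.tiff`/`.png`).
#' @param pixel_size_nm pixel size to attach (nm/pixel).
#' @return an [image_plane()].
#' @export
read_image <- function(path, pixel_size_nm = 1.11) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext, " (", path, ")"))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  image_plane(img, pixel_size_nm = pixel_size_nm)
}

#' Write a single-channel image (TIFF or PNG)
#'
#' @param image matrix or [image_plane()] with values in `[0, 1]`; values
#'   are clipped to that range before writing.
#' @param path destination; format chosen by extension.
#' @param bits bit depth for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  m <- pmin(pmax(as_plain_matrix(unclass(image)), 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits)),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext, " (", path, ")"))
  invisible(path)
}

# Separable Gaussian blur with symmetric (reflected, edge-included) borders.
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(m); n2 <- ncol(m)
  pad_idx <- function(t, n) {           # symmetric reflection, 0-based
    mmod <- ((t %% (2 * n)) + 2 * n) %% (2 * n)
    ifelse(mmod < n, mmod, 2 * n - 1 - mmod)
  }
  rows <- pad_idx((-r):(n1 - 1 + r), n1) + 1L
  padded <- m[rows, , drop = FALSE]
  out <- matrix(0, n1, n2)
  for (t in seq_along(k))
    out <- out + k[t] * padded[t:(t + n1 - 1L), , drop = FALSE]
  cols <- pad_idx((-r):(n2 - 1 + r), n2) + 1L
  padded <- out[, cols, drop = FALSE]
  out2 <- matrix(0, n1, n2)
  for (t in seq_along(k))
    out2 <- out2 + k[t] * padded[, t:(t + n2 - 1L), drop = FALSE]
  out2
}
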