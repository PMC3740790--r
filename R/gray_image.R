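#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of finite intensities in
#' `[0, max_intensity]`, stored with rows as image rows (y, increasing
#' downward) and columns as image columns (x, increasing rightward).
#' Intensities are integer-valued by default (8-bit, `max_intensity = 255`);
#' wider integer ranges are permitted, e.g. for the all-distinct
#' "unique-ramp" texture.
#'
#' @param x numeric matrix of pixel intensities.
#' @param max_intensity maximum representable intensity (default 255).
#' @return an object of class `gray_image` (a classed matrix with a
#'   `max_intensity` attribute).
#' @export
gray_image <- function(x, max_intensity = 255) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  if (min(x) < 0 || max(x) > max_intensity) {
    stop("image intensities must lie in [0, ", max_intensity, "]",
         call. = FALSE)
  }
  structure(x, class = c("gray_image", "matrix"),
            max_intensity = max_intensity)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d (height x width), intensities [%g, %g] of [0, %g]\n",
              nrow(x), ncol(x), min(x), max(x), max_intensity_of(x)))
  invisible(x)
}

#' Test for the gray_image class
#' @param x object to test.
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

#' Coerce to gray_image
#' @inheritParams gray_image
#' @export
as_gray_image <- function(x, max_intensity = 255) {
  if (is_gray_image(x)) return(x)
  gray_image(as.matrix(x), max_intensity = max_intensity)
}

max_intensity_of <- function(x) {
  mi <- attr(x, "max_intensity")
  if (is.null(mi)) 255 else mi
}

# strip class/attributes for raw matrix arithmetic
img_mat <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

assert_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical shapes (%s vs %s)", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a grayscale image from PNG or TIFF
#'
#' 8-bit single-channel files map to intensities 0..255; multi-channel input
#' is averaged to grayscale.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param max_intensity intensity ceiling of the decoded image.
#' @return a [gray_image].
#' @export
read_gray_image <- function(path, max_intensity = 255) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(raw)) == 3) raw <- apply(raw, c(1, 2), mean)
  gray_image(round(raw * max_intensity), max_intensity = max_intensity)
}

#' Write a grayscale image to PNG or TIFF
#'
#' @param image a [gray_image] (or plain matrix, interpreted as 8-bit).
#' @param path destination path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  image <- as_gray_image(image, max_intensity = max(255, max(image)))
  norm <- img_mat(image) / max_intensity_of(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(norm, target = path),
    tif  = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Pixel-level view of an image as a tibble
#'
#' One row per pixel with columns `x` (column, 0-based), `y` (row, 0-based)
#' and `intensity`; convenient for ggplot2 and dplyr work.
#'
#' @param x a [gray_image].
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.gray_image <- function(x, ...) {
  h <- nrow(x); w <- ncol(x)
  tibble::tibble(
    x = rep(seq_len(w) - 1L, each = h),
    y = rep(seq_len(h) - 1L, times = w),
    intensity = as.vector(img_mat(x))
  )
}
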