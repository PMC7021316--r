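#' RGB image containers and PNG input/output
#'
#' Micrographs are plain numeric arrays of shape `height x width x 3` holding
#' 8-bit sRGB values in `[0, 255]`; region-of-interest (ROI) masks are logical
#' matrices. `as_rgb_image()` validates/coerces, the `read_*`/`write_*`
#' helpers move them to and from 8-bit PNG (masks are written as single
#' channel, 255 = inside ROI).
#'
#' @param x numeric array `h x w x 3`, values in `[0, 255]`.
#' @return `as_rgb_image()` returns the validated array with class
#'   `rgb_image`.
#' @examples
#' img <- as_rgb_image(array(128, dim = c(4, 4, 3)))
#' @export
as_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    abort_data("an RGB image must be a numeric h x w x 3 array")
  if (!all(is.finite(x)) || min(x) < 0 || max(x) > 255)
    abort_data("RGB image values must be finite and within [0, 255]")
  structure(x, class = "rgb_image")
}

#' @rdname as_rgb_image
#' @param path file path of an 8-bit PNG.
#' @export
read_image_png <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("image file not found: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  else a <- array(a[, , 1L], dim = c(dim(a)[1:2], 3L))
  as_rgb_image(round(a * 255))
}

#' @rdname as_rgb_image
#' @param img an `rgb_image`.
#' @export
write_image_png <- function(img, path) {
  img <- as_rgb_image(unclass(img))
  png::writePNG(unclass(img) / 255, target = path)
  invisible(path)
}

#' @rdname as_rgb_image
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("mask file not found: %s", path))
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a >= 0.5
}

#' @rdname as_rgb_image
#' @param mask logical matrix, `TRUE` = inside ROI.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(ifelse(mask, 1, 0), target = path)
  invisible(path)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, 8-bit sRGB>\n", d[1], d[2]))
  invisible(x)
}

# 8-bit quantization of a [0,1]-scaled channel/array.
quantize8 <- function(x) round(pmin(pmax(x, 0), 1) * 255)
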