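## Image container.
##
## Images are stored as numeric arrays `a[row, col, channel]` with intensities
## on the integer grid [0, 255] and exactly three channels. Row index is the
## image y coordinate (top to bottom), column index is x. An optional
## `scale_factor` attribute records the ratio working-size / original-size so
## measurements can be mapped back to original-image pixels.

#' Construct a stomata pipeline image
#'
#' Wraps a numeric array as a 3-channel, 8-bit image. Grayscale (2-d) input is
#' replicated across three channels. Inputs on other scales (16-bit integer or
#' floating point in \[0, 1\]) are linearly rescaled to \[0, 255\].
#'
#' @param x A numeric matrix (grayscale) or `h x w x 3` array.
#' @param scale_factor Ratio of working size to original size (1 when the
#'   image is at its native resolution).
#' @return An object of class `stoma_image`: a `h x w x 3` integer-valued
#'   array in \[0, 255\] with a `scale_factor` attribute.
#' @export
stoma_image <- function(x, scale_factor = 1) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (length(dim(x)) != 3L || dim(x)[3] != 3L) {
    abort("`x` must be a matrix or an array with exactly 3 channels.")
  }
  if (anyNA(x)) abort("image contains NA intensities")
  mx <- max(x)
  if (mx <= 1 && min(x) >= 0) {
    x <- x * 255
  } else if (mx > 255) {
    ## 16-bit (or other deep) input: rescale full range linearly
    x <- (x - min(x)) / max(mx - min(x), .Machine$double.eps) * 255
  }
  x <- round(pmin(pmax(x, 0), 255))
  structure(x, scale_factor = scale_factor, class = "stoma_image")
}

#' @export
print.stoma_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<stoma_image> %d x %d px, 3 channels, scale_factor = %.4g\n",
    d[2], d[1], scale_factor(x)
  ))
  invisible(x)
}

#' @rdname stoma_image
#' @export
is_stoma_image <- function(x) inherits(x, "stoma_image")

#' @rdname stoma_image
#' @export
scale_factor <- function(x) attr(x, "scale_factor") %||% 1

image_dim <- function(img) dim(img)[1:2] # (h, w)

## EBImage stores arrays as [x, y, channel]; ours are [row, col, channel].
to_ebimage <- function(img) {
  EBImage::Image(aperm(unclass(img) / 255, c(2, 1, 3)), colormode = "Color")
}

from_ebimage <- function(ebi, scale_factor = 1) {
  a <- EBImage::imageData(ebi)
  if (length(dim(a)) == 2L) {
    a <- t(a)
  } else {
    if (dim(a)[3] > 3L) a <- a[, , 1:3] # drop alpha
    if (dim(a)[3] == 1L) a <- a[, , 1]
    a <- if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  }
  stoma_image(a, scale_factor = scale_factor)
}

#' Read an image file
#'
#' Reads JPEG, PNG or TIFF microscope images. Single-channel images are
#' replicated to three channels; 16-bit data are rescaled to 8-bit.
#'
#' @param path Path to a JPEG/PNG/TIFF file.
#' @return A [stoma_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) abort(paste0("image file not found: ", path))
  from_ebimage(EBImage::readImage(path))
}

#' Write an image file
#'
#' @param img A [stoma_image].
#' @param path Output path; format chosen from the extension (`.png`
#'   lossless by default, `.jpg`/`.jpeg` and `.tif`/`.tiff` also supported).
#' @param quality JPEG quality (ignored for other formats).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, quality = 95) {
  stopifnot(is_stoma_image(img))
  EBImage::writeImage(to_ebimage(img), path, quality = quality)
  invisible(path)
}
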