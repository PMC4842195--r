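# Images are plain matrices: height x width, one value per pixel.
# 8-bit images hold integers in [0, 255] (stored as numeric or integer);
# gradient surfaces are float-valued matrices with the same shape contract.
# RGB images are height x width x 3 arrays of 8-bit values.

assert_gray <- function(img, arg = deparse(substitute(img))) {
  if (!is.matrix(img) || !is.numeric(img))
    stop(sprintf("'%s' must be a numeric matrix (single-channel image)", arg))
  if (nrow(img) < 1L || ncol(img) < 1L)
    stop(sprintf("'%s' must have at least one row and one column", arg))
  invisible(img)
}

assert_gray8 <- function(img, arg = deparse(substitute(img))) {
  assert_gray(img, arg)
  if (anyNA(img) || any(img < 0) || any(img > 255) || any(img != round(img)))
    stop(sprintf("'%s' must be an 8-bit image: integer values in [0, 255]", arg))
  invisible(img)
}

assert_rgb <- function(img, arg = deparse(substitute(img))) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("'%s' must be a height x width x 3 array", arg))
  if (anyNA(img) || any(img < 0) || any(img > 255))
    stop(sprintf("'%s' must hold 8-bit values in [0, 255]", arg))
  invisible(img)
}

assert_connectivity <- function(connectivity) {
  if (!(length(connectivity) == 1L && connectivity %in% c(4, 8)))
    stop("'connectivity' must be 4 or 8")
  as.integer(connectivity)
}

#' Complement of an 8-bit image
#'
#' Maps every pixel value v to 255 - v. The complement is an involution:
#' applying it twice returns the original image.
#'
#' @param img numeric matrix with integer values in \code{[0, 255]}.
#' @return A matrix of the same shape with values \code{255 - img}.
#' @examples
#' complement(matrix(c(0, 255, 100, 30), 2, 2))
#' @export
complement <- function(img) {
  assert_gray8(img)
  255 - img
}

#' Convert an RGB image to 8-bit grayscale
#'
#' Applies the standard luma weighting 0.2989 R + 0.5870 G + 0.1140 B,
#' rounds half-up to the nearest integer and clips to \code{[0, 255]}.
#' Gray-valued inputs (v, v, v) map to v for every v in 0..255.
#'
#' @param img height x width x 3 array of 8-bit values.
#' @return A height x width matrix of integers in \code{[0, 255]}.
#' @export
rgb_to_gray <- function(img) {
  assert_rgb(img)
  g <- 0.2989 * img[, , 1] + 0.5870 * img[, , 2] + 0.1140 * img[, , 3]
  g <- matrix(floor(g + 0.5), dim(img)[1], dim(img)[2])  # round half-up
  pmin(pmax(g, 0), 255)
}

#' Expand a grayscale image to a 3-channel array
#'
#' @param img single-channel image matrix.
#' @return height x width x 3 array with the image replicated per channel.
#' @export
gray_to_rgb <- function(img) {
  assert_gray(img)
  array(rep(img, 3L), dim = c(dim(img), 3L))
}

# clamp + round a float image back into 8-bit range
clip8 <- function(img) pmin(pmax(round(img), 0), 255)
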