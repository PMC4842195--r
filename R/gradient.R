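#' Sobel gradient magnitude
#'
#' Correlates the image with the 3x3 horizontal and vertical Sobel kernels
#' (weights 1 and 2) under replicate border padding and returns
#' \code{sqrt(gx^2 + gy^2)}. The output is kept float-valued: rescaling the
#' magnitude to 8 bits would merge shallow basins and change the watershed
#' topology, so quantization is left to the visualization/export path.
#'
#' An interior pixel of a unit-slope horizontal ramp has magnitude 8
#' (kernel weights 1+2+1 acting across a two-column span); a 0|255 vertical
#' step yields magnitude 1020 on the two columns flanking the step.
#'
#' @param img single-channel numeric image matrix.
#' @return A non-negative float-valued matrix of the same shape.
#' @export
sobel_gradient_magnitude <- function(img) {
  if (is.array(img) && length(dim(img)) == 3L)
    stop("multi-channel input: convert with rgb_to_gray() first")
  assert_gray(img)
  h <- nrow(img); w <- ncol(img)
  # replicate padding via index clamping
  up    <- img[c(1, seq_len(h - 1)), , drop = FALSE]
  down  <- img[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  shift <- function(m, dj) {
    jj <- pmin(pmax(seq_len(w) + dj, 1L), w)
    m[, jj, drop = FALSE]
  }
  # gx: horizontal derivative (across columns); gy: vertical (across rows)
  gx <- (shift(up, 1) + 2 * shift(img, 1) + shift(down, 1)) -
        (shift(up, -1) + 2 * shift(img, -1) + shift(down, -1))
  gy <- (shift(down, -1) + 2 * down + shift(down, 1)) -
        (shift(up, -1) + 2 * up + shift(up, 1))
  sqrt(gx^2 + gy^2)
}
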