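#' Structuring elements
#'
#' A structuring element is a binary footprint over an odd-sized window with
#' an origin at the window center; the origin cell must belong to the
#' footprint. \code{se_disk} builds a discrete disk (cells with center
#' distance at most \code{radius}), \code{se_square} a full
#' \code{(2 radius + 1)} square, and \code{structuring_element} wraps an
#' arbitrary logical footprint.
#'
#' @param radius disk radius / half-width of the square, in pixels
#'   (\code{radius >= 1}).
#' @param footprint logical matrix with odd dimensions.
#' @return An object of class \code{"structuring_element"}: a list with
#'   elements \code{footprint} (logical matrix) and \code{origin}
#'   (1-based row/column of the center cell).
#' @examples
#' se_disk(1)   # the 4-connected cross
#' se_square(1) # the 3x3 square
#' @export
structuring_element <- function(footprint) {
  if (!is.matrix(footprint) || !is.logical(footprint))
    stop("'footprint' must be a logical matrix")
  if (nrow(footprint) %% 2L == 0L || ncol(footprint) %% 2L == 0L)
    stop("'footprint' must have odd dimensions")
  origin <- c((nrow(footprint) + 1L) %/% 2L, (ncol(footprint) + 1L) %/% 2L)
  if (!footprint[origin[1], origin[2]])
    stop("the origin cell must belong to the footprint")
  if (!any(footprint))
    stop("'footprint' must contain at least one cell")
  structure(list(footprint = footprint, origin = origin),
            class = "structuring_element")
}

#' @rdname structuring_element
#' @export
se_disk <- function(radius) {
  radius <- check_radius(radius)
  d <- 2L * radius + 1L
  ix <- seq_len(d) - radius - 1L
  fp <- outer(ix^2, ix^2, "+") <= radius^2
  structuring_element(fp)
}

#' @rdname structuring_element
#' @export
se_square <- function(radius) {
  radius <- check_radius(radius)
  d <- 2L * radius + 1L
  structuring_element(matrix(TRUE, d, d))
}

check_radius <- function(radius) {
  if (!(length(radius) == 1L && is.numeric(radius) &&
        radius >= 1 && radius == round(radius)))
    stop("'radius' must be a positive integer")
  as.integer(radius)
}

assert_se <- function(se) {
  if (!inherits(se, "structuring_element"))
    stop("'se' must be a structuring_element (see se_disk(), se_square())")
  invisible(se)
}

# 180-degree rotation of the footprint, used by dilation
reflect_se <- function(se) {
  fp <- se$footprint[rev(seq_len(nrow(se$footprint))),
                     rev(seq_len(ncol(se$footprint))), drop = FALSE]
  structuring_element(fp)
}

#' Default structuring element for an image
#'
#' The enhancement stage is scale-relative by default: a disk of radius
#' \code{max(3, round(0.02 * min(height, width)))}, so the same settings
#' behave comparably across image sizes. Shape and radius are configurable
#' everywhere a structuring element is accepted.
#'
#' @param img image matrix the element will be applied to.
#' @param shape \code{"disk"} or \code{"square"}.
#' @param radius optional explicit radius overriding the scale-relative rule.
#' @return A \code{structuring_element}.
#' @export
default_se <- function(img, shape = c("disk", "square"), radius = NULL) {
  assert_gray(img)
  shape <- match.arg(shape)
  if (is.null(radius))
    radius <- max(3L, as.integer(round(0.02 * min(dim(img)))))
  switch(shape, disk = se_disk(radius), square = se_square(radius))
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring element: %dx%d footprint, %d cells set\n",
              nrow(x$footprint), ncol(x$footprint), sum(x$footprint)))
  invisible(x)
}
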