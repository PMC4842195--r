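# Grayscale morphology: flat erosion/dilation, geodesic reconstruction and
# the reconstruction-based opening/closing filters, plus the four-step HMR
# enhancement chain built from them.

#' Flat grayscale erosion and dilation
#'
#' \code{erode} replaces each pixel by the minimum of the image over the
#' structuring-element footprint centered there; \code{dilate} takes the
#' maximum over the reflected footprint. At the border the footprint is
#' restricted to the image domain, so no out-of-range padding value is ever
#' invented.
#'
#' @param img numeric image matrix.
#' @param se a \code{\link{structuring_element}}.
#' @return A matrix of the same shape.
#' @examples
#' img <- matrix(0, 5, 5); img[3, 3] <- 255
#' erode(img, se_square(1))   # wipes the isolated peak
#' dilate(img, se_square(1))  # grows it to a 3x3 block
#' @export
erode <- function(img, se) {
  assert_gray(img)
  assert_se(se)
  cpp_minmax_filter(img, se$footprint,
                    se$origin[1] - 1L, se$origin[2] - 1L, FALSE)
}

#' @rdname erode
#' @export
dilate <- function(img, se) {
  assert_gray(img)
  assert_se(se)
  se <- reflect_se(se)
  cpp_minmax_filter(img, se$footprint,
                    se$origin[1] - 1L, se$origin[2] - 1L, TRUE)
}

#' Grayscale geodesic reconstruction
#'
#' \code{reconstruct_by_dilation} iterates "dilate the marker by the unit
#' connectivity neighborhood, then clip pointwise to the mask" to its fixed
#' point, propagating marker peaks through connected regions where the mask
#' allows. The result r satisfies \code{marker <= r <= mask} and is itself a
#' fixed point. \code{reconstruct_by_erosion} is the dual (marker above the
#' mask, descending), defined by complementing a reconstruction by dilation.
#'
#' The implementation uses a raster-sweep + queue algorithm; its semantics
#' are exactly the iterated-geodesic-dilation limit.
#'
#' @param marker,mask numeric matrices of the same shape, with
#'   \code{marker <= mask} everywhere (\code{>=} for the erosion variant).
#' @param connectivity pixel neighborhood, 4 or 8 (default 8).
#' @return The reconstructed image matrix.
#' @export
reconstruct_by_dilation <- function(marker, mask, connectivity = 8) {
  assert_gray(marker); assert_gray(mask)
  connectivity <- assert_connectivity(connectivity)
  if (!identical(dim(marker), dim(mask)))
    stop("'marker' and 'mask' must have identical dimensions")
  if (any(marker > mask))
    stop("'marker' must not exceed 'mask' anywhere")
  cpp_reconstruct_dilation(marker, mask, connectivity)
}

#' @rdname reconstruct_by_dilation
#' @export
reconstruct_by_erosion <- function(marker, mask, connectivity = 8) {
  assert_gray(marker); assert_gray(mask)
  connectivity <- assert_connectivity(connectivity)
  if (!identical(dim(marker), dim(mask)))
    stop("'marker' and 'mask' must have identical dimensions")
  if (any(marker < mask))
    stop("'marker' must not be below 'mask' anywhere")
  # dual through an exact sign flip (works for float surfaces too)
  -cpp_reconstruct_dilation(-marker, -mask, connectivity)
}

#' Opening- and closing-by-reconstruction
#'
#' \code{opening_by_reconstruction} erodes the image with \code{se} and
#' reconstructs it by dilation under the original: bright structures smaller
#' than the footprint are removed while the shapes of survivors are restored
#' exactly. It is anti-extensive (output <= input) and idempotent.
#' \code{closing_by_reconstruction} is the complement-dual filter (dark
#' structures removed; extensive, idempotent), computed on 8-bit images as
#' \code{255 - opening_by_reconstruction(255 - img, se)}.
#'
#' @inheritParams erode
#' @param connectivity reconstruction neighborhood, 4 or 8.
#' @return A matrix of the same shape.
#' @export
opening_by_reconstruction <- function(img, se, connectivity = 8) {
  reconstruct_by_dilation(erode(img, se), img, connectivity)
}

#' @rdname opening_by_reconstruction
#' @export
closing_by_reconstruction <- function(img, se, connectivity = 8) {
  assert_gray8(img)
  complement(opening_by_reconstruction(complement(img), se, connectivity))
}

#' Hybrid morphological reconstruction (HMR) enhancement
#'
#' The four-step enhancement chain for 8-bit images: complement the image,
#' apply opening-by-reconstruction, then closing-by-reconstruction, and
#' complement back into the original intensity space. The two
#' reconstruction filters flatten small bright and dark structures (noise,
#' speckle) below the structuring-element scale while leaving the contours
#' of larger structures untouched, which is what makes the subsequent
#' gradient/watershed stages stable.
#'
#' @inheritParams opening_by_reconstruction
#' @return An 8-bit image matrix of the same shape.
#' @export
hmr_enhance <- function(img, se = default_se(img), connectivity = 8) {
  assert_gray8(img)
  r_c <- complement(img)
  r_obr <- opening_by_reconstruction(r_c, se, connectivity)
  r_obrcbr <- closing_by_reconstruction(r_obr, se, connectivity)
  complement(r_obrcbr)
}

#' Regional maxima and minima
#'
#' A regional maximum is a connected plateau of constant intensity all of
#' whose external boundary pixels are strictly lower (for minima, strictly
#' higher). A plateau touching the image border is judged by its existing
#' neighbors only, and a constant image is one single plateau with no
#' external boundary, hence entirely a regional maximum.
#'
#' @param img numeric image matrix (integer or float valued).
#' @param connectivity plateau/neighbor connectivity, 4 or 8.
#' @return A logical matrix marking the extremal plateaus.
#' @export
regional_maxima <- function(img, connectivity = 8) {
  assert_gray(img)
  connectivity <- assert_connectivity(connectivity)
  cpp_regional_maxima(img, connectivity)
}

#' @rdname regional_maxima
#' @export
regional_minima <- function(img, connectivity = 8) {
  assert_gray(img)
  connectivity <- assert_connectivity(connectivity)
  cpp_regional_maxima(-img, connectivity)
}

#' Connected components of a binary mask
#'
#' Labels the connected components 1..K in raster (column-major) order of
#' each component's first pixel; background is 0.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return An integer matrix of component labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix")
  connectivity <- assert_connectivity(connectivity)
  cpp_label_components(mask, connectivity)
}
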