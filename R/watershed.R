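# Watershed transform by immersion, minima imposition for marker control,
# and overlay rendering.

#' Watershed transform of a topographic surface
#'
#' The surface is viewed as topography and flooded from below: each regional
#' minimum seeds one catchment basin, pixels are processed in increasing
#' surface order, and a pixel drains into the basin of its steepest
#' (minimum-valued) lower neighbors — first arrival in FIFO order across
#' plateaus. Pixels whose water would reach two or more distinct basins
#' (tied steepest routes, or geodesically equidistant plateau conflicts)
#' become watershed-line pixels with label 0. Basins are numbered 1..K by
#' raster order of their seeding minimum.
#'
#' @param surface float-valued matrix of finite values.
#' @param connectivity pixel neighborhood, 4 or 8.
#' @return An integer label matrix: 0 = watershed line, k >= 1 = basin k.
#' @examples
#' watershed_flood(matrix(c(0, 1, 2, 1, 0), 1))  # two basins, center divide
#' @export
watershed_flood <- function(surface, connectivity = 8) {
  assert_gray(surface)
  connectivity <- assert_connectivity(connectivity)
  if (anyNA(surface) || any(!is.finite(surface)))
    stop("'surface' must be finite everywhere")
  cpp_watershed(surface, connectivity)
}

#' Minima imposition
#'
#' Modifies a surface so that its regional minima are exactly the connected
#' components of a marker mask: marker pixels are forced below the global
#' minimum and all other pixels are raised by a geodesic
#' reconstruction-by-erosion of \code{pmin(surface + step, forced)} under
#' the forced image, which removes every spurious minimum. Flooding the
#' result grows one basin per marker component.
#'
#' @param surface float-valued matrix.
#' @param markers logical matrix of seed pixels; must contain at least one.
#' @param connectivity 4 or 8.
#' @param step positive level offset separating non-marker pixels from the
#'   original surface; 1 intensity unit by default (any positive value
#'   works; 1 matches the 8-bit scale the gradients derive from).
#' @return The modified surface matrix.
#' @export
impose_minima <- function(surface, markers, connectivity = 8, step = 1) {
  assert_gray(surface)
  connectivity <- assert_connectivity(connectivity)
  if (!is.matrix(markers) || !is.logical(markers) ||
      !identical(dim(markers), dim(surface)))
    stop("'markers' must be a logical matrix matching the surface shape")
  if (!any(markers))
    stop("'markers' must contain at least one seed pixel")
  if (!(is.numeric(step) && length(step) == 1L && step > 0))
    stop("'step' must be a positive number")
  lo <- min(surface) - step
  hi <- max(surface) + 2 * step
  forced <- matrix(hi, nrow(surface), ncol(surface))
  forced[markers] <- lo
  mask <- pmin(surface + step, forced)
  reconstruct_by_erosion(forced, mask, connectivity)
}

#' Marker-controlled watershed
#'
#' Imposes the marker components as the only regional minima of the surface
#' and floods: the partition has exactly one basin per marker component.
#' Markers are typically the regional maxima of the HMR-enhanced image and
#' the surface its Sobel gradient magnitude, so basins grow from homogeneous
#' structure interiors and meet on intensity edges.
#'
#' @inheritParams impose_minima
#' @param marker_labels optional integer matrix pre-labeling the marker
#'   components (nonzero = seed); overrides the raster-order component
#'   numbering and lets callers control label assignment. Components must
#'   be consistent with \code{markers} when both are given.
#' @return An integer label matrix (0 = watershed line).
#' @export
marker_watershed <- function(surface, markers, connectivity = 8,
                             marker_labels = NULL) {
  if (!is.null(marker_labels)) {
    if (!is.matrix(marker_labels) || !is.numeric(marker_labels))
      stop("'marker_labels' must be an integer matrix")
    markers <- marker_labels > 0
  }
  lab <- watershed_flood(impose_minima(surface, markers, connectivity),
                         connectivity)
  if (!is.null(marker_labels)) {
    # remap raster-order basin ids onto the caller's marker labels; a
    # marker component that the flood connectivity splits (e.g. a
    # diagonal-only link under 4-connectivity) maps all its basins onto
    # the one caller id, merging them
    map <- integer(max(lab))
    for (id in sort(unique(marker_labels[marker_labels > 0]))) {
      inside <- lab[marker_labels == id]
      inside <- unique(inside[inside > 0])
      map[inside] <- id
    }
    pos <- lab > 0
    lab[pos] <- map[lab[pos]]
  }
  lab
}

#' Superimpose watershed lines on an image
#'
#' Returns the original image with watershed-line pixels (label 0) painted
#' in the given color, the standard way of presenting a segmentation over
#' its source image.
#'
#' @param original height x width x 3 array of 8-bit values.
#' @param labels integer label matrix from a watershed transform.
#' @param color length-3 vector of 8-bit RGB values for the divide lines.
#' @return A height x width x 3 array.
#' @export
superimpose <- function(original, labels, color = c(255, 0, 0)) {
  assert_rgb(original)
  if (!is.matrix(labels) || !identical(dim(labels), dim(original)[1:2]))
    stop("'labels' shape must match the image")
  if (length(color) != 3L || any(color < 0) || any(color > 255))
    stop("'color' must be three 8-bit values")
  out <- original
  lines <- labels == 0
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[lines] <- color[ch]
    out[, , ch] <- plane
  }
  out
}
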