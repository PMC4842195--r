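# Raster and table I/O. 8-bit grayscale/RGB rasters go through PNG or
# TIFF; label maps through 16-bit TIFF (lossless for up to 65535 basins),
# 8-bit PNG when the label count fits, or a run-length CSV.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext))
}

#' Read and write 8-bit raster images
#'
#' \code{read_image} loads a PNG or TIFF file and returns an 8-bit matrix
#' (grayscale) or height x width x 3 array (color; an alpha channel, if
#' present, is dropped). \code{write_image} is the inverse; the round-trip
#' is lossless for 8-bit data. Malformed files raise a format error.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param img 8-bit image matrix or 3-channel array; float matrices (e.g.
#'   gradient magnitudes) are affinely rescaled to 0..255 for export.
#' @return \code{read_image}: the image; \code{write_image}: the path,
#'   invisibly.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path))
  fmt <- img_format(path)
  raw01 <- tryCatch(
    if (fmt == "png") png::readPNG(path) else tiff::readTIFF(path),
    error = function(e)
      stop(sprintf("malformed or unreadable %s file '%s': %s",
                   toupper(fmt), path, conditionMessage(e)), call. = FALSE))
  img <- round(raw01 * 255)
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] >= 3L) img <- img[, , 1:3, drop = FALSE]
    else img <- matrix(img[, , 1], dim(img)[1], dim(img)[2])
  }
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  fmt <- img_format(path)
  if (is.matrix(img) && (any(img > 255) || any(img != round(img)))) {
    rng <- range(img)
    img <- if (rng[2] > rng[1])
      round((img - rng[1]) / (rng[2] - rng[1]) * 255) else img * 0
  }
  if (is.matrix(img)) assert_gray8(img) else assert_rgb(img)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (fmt == "png") png::writePNG(img / 255, path)
  else tiff::writeTIFF(img / 255, path, bits.per.sample = 8L,
                       compression = "none")
  invisible(path)
}

#' Read and write watershed label maps
#'
#' TIFF paths store labels losslessly at 16 bits per sample; PNG paths use
#' 8 bits and therefore require at most 255 basins; CSV paths store a
#' column-major run-length encoding (columns \code{value}, \code{length})
#' with the image dimensions on the first row.
#'
#' @param labels integer label matrix (0 = watershed line).
#' @param path destination ending in .tif/.tiff, .png or .csv.
#' @return \code{write_labels}: the path, invisibly; \code{read_labels}:
#'   the integer label matrix.
#' @export
write_labels <- function(labels, path) {
  if (!is.matrix(labels) || any(labels < 0) || any(labels != round(labels)))
    stop("'labels' must be a matrix of non-negative integers")
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (ext == "csv") {
    r <- rle(as.integer(labels))
    df <- data.frame(value = c(nrow(labels), r$values),
                     length = c(ncol(labels), r$lengths))
    write.csv(df, path, row.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    if (max(labels) > 65535) stop("more than 65535 labels")
    tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  } else if (ext == "png") {
    if (max(labels) > 255)
      stop("PNG label export is 8-bit; use a .tif path for > 255 basins")
    png::writePNG(labels / 255, path)
  } else stop(sprintf("unsupported label format '.%s'", ext))
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    df <- read.csv(path)
    h <- df$value[1]; w <- df$length[1]
    matrix(inverse.rle(list(values = df$value[-1],
                            lengths = df$length[-1])), h, w)
  } else if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  } else if (ext == "png") {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  } else stop(sprintf("unsupported label format '.%s'", ext))
}

#' Write a statistics table
#'
#' Exports a per-basin metric table (see \code{\link{basin_stats}}) as CSV
#' or JSON, keyed by the file extension. The column schema is the table's
#' own: basin, area, perimeter, channel, sd, skewness, median.
#'
#' @param table a data.frame.
#' @param path destination ending in .csv or .json.
#' @return The path, invisibly.
#' @export
write_stats <- function(table, path) {
  if (!is.data.frame(table)) stop("'table' must be a data.frame")
  ext <- tolower(tools::file_ext(path))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (ext == "csv") write.csv(table, path, row.names = FALSE)
  else if (ext == "json")
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA)
  else stop(sprintf("unsupported stats format '.%s'", ext))
  invisible(path)
}
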