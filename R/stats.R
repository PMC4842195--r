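# MIPAV-style ROI quality metrics: area, perimeter, and per-channel
# intensity statistics, plus the before/after severity-trend report.

#' ROI area and perimeter
#'
#' \code{roi_area} counts the set pixels of a binary mask.
#' \code{roi_perimeter} counts unit pixel edges between a set pixel and
#' either an unset pixel or the image border, so a solid w x h rectangle
#' has perimeter exactly 2(w + h). Both depend only on the mask, never on
#' image values.
#'
#' @param mask logical matrix delineating the region.
#' @return A single number: pixel count / unit-edge count.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2:3, 2:4] <- TRUE
#' roi_area(m)       # 6
#' roi_perimeter(m)  # 10
#' @export
roi_area <- function(mask) {
  assert_mask(mask)
  sum(mask)
}

#' @rdname roi_area
#' @export
roi_perimeter <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  core <- pad[2:(h + 1), 2:(w + 1)]
  exposed <- (core & !pad[1:h, 2:(w + 1)]) +       # above
             (core & !pad[3:(h + 2), 2:(w + 1)]) + # below
             (core & !pad[2:(h + 1), 1:w]) +       # left
             (core & !pad[2:(h + 1), 3:(w + 2)])   # right
  sum(exposed)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("'mask' must be a logical matrix")
  invisible(mask)
}

#' Per-channel intensity statistics over an ROI
#'
#' For each channel, over the masked pixels: the standard deviation
#' (population convention sqrt(m2) by default, with a switch for the n - 1
#' sample variant), the Fisher-Pearson skewness g1 = m3 / m2^(3/2) (defined
#' as 0 when m2 = 0), and the median with the lower-of-two-middles rule for
#' even counts, which keeps medians of integer data deterministic and
#' integer-valued.
#'
#' @param img single-channel matrix or height x width x channels array.
#' @param mask logical matrix; must contain at least one pixel.
#' @param sample if TRUE use the n - 1 (sample) convention for the standard
#'   deviation; skewness stays the population g1.
#' @return A data.frame with one row per channel: \code{channel}, \code{sd},
#'   \code{skewness}, \code{median}.
#' @export
roi_intensity_stats <- function(img, mask, sample = FALSE) {
  assert_mask(mask)
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("'img' must be a matrix or a height x width x channels array")
  if (!identical(dim(img)[1:2], dim(mask)))
    stop("'img' and 'mask' shapes must match")
  if (!any(mask))
    stop("empty ROI: mask has no set pixels")
  nch <- dim(img)[3]
  out <- data.frame(channel = seq_len(nch), sd = NA_real_,
                    skewness = NA_real_, median = NA_real_)
  for (ch in seq_len(nch)) {
    v <- img[, , ch][mask]
    n <- length(v)
    m <- mean(v)
    m2 <- mean((v - m)^2)
    m3 <- mean((v - m)^3)
    out$sd[ch] <- if (sample && n > 1) sqrt(m2 * n / (n - 1)) else sqrt(m2)
    out$skewness[ch] <- if (m2 > 0) m3 / m2^1.5 else 0
    out$median[ch] <- sort(v)[(n + 1L) %/% 2L]  # lower of two middles
  }
  out
}

#' Full metric panel for one ROI
#'
#' Bundles area, perimeter and the per-channel intensity statistics into an
#' \code{roi_stats} record, the per-region analogue of a quality-metric
#' table row.
#'
#' @inheritParams roi_intensity_stats
#' @return An object of class \code{"roi_stats"}: list with \code{area},
#'   \code{perimeter}, and \code{channels} (the per-channel data.frame).
#' @export
roi_stats <- function(img, mask, sample = FALSE) {
  area <- roi_area(mask)
  if (area == 0)
    stop("empty ROI: mask has no set pixels")
  structure(list(area = area,
                 perimeter = roi_perimeter(mask),
                 channels = roi_intensity_stats(img, mask, sample)),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI: area %d px, perimeter %d unit edges\n",
              x$area, x$perimeter))
  print(x$channels, row.names = FALSE)
  invisible(x)
}

#' Per-basin metric table for a label image
#'
#' Computes the ROI metric panel for every basin of a watershed label image
#' against a reference image (typically the original, pre-enhancement
#' intensities, so the measurement is not conflated with the enhancement).
#'
#' @param img reference image (matrix or 3-channel array).
#' @param labels integer label matrix (0 = watershed line, ignored).
#' @inheritParams roi_intensity_stats
#' @return A data.frame with one row per basin per channel: \code{basin},
#'   \code{area}, \code{perimeter}, \code{channel}, \code{sd},
#'   \code{skewness}, \code{median}.
#' @export
basin_stats <- function(img, labels, sample = FALSE) {
  if (!is.matrix(labels) || !is.numeric(labels))
    stop("'labels' must be an integer matrix")
  ks <- sort(unique(labels[labels > 0]))
  rows <- lapply(ks, function(k) {
    s <- roi_stats(img, labels == k, sample)
    cbind(basin = k, area = s$area, perimeter = s$perimeter, s$channels)
  })
  do.call(rbind, rows)
}

#' Severity-trend report between two ROI measurements
#'
#' Compares a baseline and a follow-up metric panel metric by metric and
#' reports the signed delta and a direction tag. The clinical reading the
#' trends support: shrinking area/perimeter of the open region means the
#' degree of severity increased; rising standard deviation means finer
#' detected edges; a median shift tracks the average pixel-level change.
#'
#' @param before,after \code{roi_stats} objects with matching channel
#'   counts.
#' @return A data.frame with columns \code{metric}, \code{channel} (NA for
#'   the shape metrics), \code{before}, \code{after}, \code{delta},
#'   \code{direction} (increase / decrease / unchanged).
#' @examples
#' m <- matrix(TRUE, 3, 3)
#' a <- roi_stats(matrix(5, 3, 3), m)
#' severity_report(a, a)  # all deltas 0, all "unchanged"
#' @export
severity_report <- function(before, after) {
  if (!inherits(before, "roi_stats") || !inherits(after, "roi_stats"))
    stop("'before' and 'after' must be roi_stats objects")
  if (nrow(before$channels) != nrow(after$channels))
    stop("channel counts differ between 'before' and 'after'")
  rows <- list(
    data.frame(metric = "area", channel = NA_integer_,
               before = before$area, after = after$area),
    data.frame(metric = "perimeter", channel = NA_integer_,
               before = before$perimeter, after = after$perimeter))
  for (metric in c("sd", "skewness", "median")) {
    rows[[length(rows) + 1L]] <-
      data.frame(metric = metric,
                 channel = before$channels$channel,
                 before = before$channels[[metric]],
                 after = after$channels[[metric]])
  }
  out <- do.call(rbind, rows)
  out$delta <- out$after - out$before
  out$direction <- ifelse(out$delta > 0, "increase",
                          ifelse(out$delta < 0, "decrease", "unchanged"))
  out
}
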