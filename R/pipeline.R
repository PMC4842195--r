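# End-to-end orchestration: input -> grayscale -> (polarity) -> HMR
# enhancement -> Sobel gradient -> markers -> watershed -> overlay ->
# per-basin ROI statistics, with every intermediate stage retained and
# optionally written to disk.

#' Pipeline configuration
#'
#' @param polarity \code{"normal"} works on the image as loaded;
#'   \code{"invert"} complements it first, for inputs whose structures of
#'   interest are dark (the enhancement chain and the regional-maxima
#'   markers both key on bright structures).
#' @param se_shape,se_radius structuring element for the enhancement;
#'   radius \code{NULL} means the scale-relative default
#'   (\code{\link{default_se}}).
#' @param connectivity pixel neighborhood (4 or 8) for the enhancement
#'   reconstructions, the minima imposition and the watershed flood;
#'   default 4. Marker extraction always treats plateaus as 8-connected
#'   (one structure, one marker); basins that a 4-connected flood splits
#'   inside one 8-connected marker are merged back. The 4-connected flood
#'   is deliberate: under 8-connectivity a flooding path can slip
#'   diagonally between two gradient-band pixels, so the effective
#'   barrier between basins degenerates to a rasterization-dependent
#'   minimum instead of scaling with the edge contrast.
#' @param marker_mode \code{"maxima"} derives foreground markers from the
#'   regional maxima of the enhanced image, \code{"none"} floods the
#'   gradient unmarked, \code{"mask"} uses \code{marker_mask}.
#' @param marker_mask logical matrix of external markers (marker_mode
#'   \code{"mask"}).
#' @param marker_min_area markers smaller than this pixel count are
#'   discarded after the consolidation step; \code{NULL} means the
#'   structuring-element footprint area.
#' @param marker_merge_depth maxima whose separating valley is at most
#'   this many intensity units deep are merged into one marker before
#'   extraction (geodesic reconstruction of \code{enhanced - depth} under
#'   \code{enhanced}). On noisy inputs the enhancement flattens a
#'   homogeneous region to its top level minus a few units, leaving
#'   one-unit-deep channels that would otherwise split the region's
#'   marker; the default of 4 is above that residual jitter and far below
#'   any structural contrast. 0 disables the merge.
#' @param legacy_order if TRUE the watershed surface is the gradient of the
#'   raw grayscale image rather than of the enhanced image (the alternative
#'   narration order some presentations of this pipeline use); markers are
#'   still taken from the enhanced image.
#' @param line_color RGB color painted on watershed lines in the overlay.
#' @param seed integer recorded in the configuration echo; the pipeline
#'   itself is deterministic, the seed feeds phantom generation when a
#'   \code{phantom_spec} is the input.
#' @return An object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(polarity = c("normal", "invert"),
                            se_shape = c("disk", "square"),
                            se_radius = NULL,
                            connectivity = 4,
                            marker_mode = c("maxima", "none", "mask"),
                            marker_mask = NULL,
                            marker_min_area = NULL,
                            marker_merge_depth = 4,
                            legacy_order = FALSE,
                            line_color = c(255, 0, 0),
                            seed = 1L) {
  polarity <- match.arg(polarity)
  se_shape <- match.arg(se_shape)
  marker_mode <- match.arg(marker_mode)
  connectivity <- assert_connectivity(connectivity)
  if (!is.null(se_radius)) se_radius <- check_radius(se_radius)
  if (marker_mode == "mask" &&
      (!is.matrix(marker_mask) || !is.logical(marker_mask)))
    stop("marker_mode 'mask' requires a logical 'marker_mask'")
  if (!(length(marker_merge_depth) == 1L && marker_merge_depth >= 0))
    stop("'marker_merge_depth' must be a non-negative number")
  structure(list(polarity = polarity, se_shape = se_shape,
                 se_radius = se_radius, connectivity = connectivity,
                 marker_mode = marker_mode, marker_mask = marker_mask,
                 marker_min_area = marker_min_area,
                 marker_merge_depth = marker_merge_depth,
                 legacy_order = isTRUE(legacy_order),
                 line_color = line_color, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Marker cleanup: (1) drop maxima components below the area floor — a
# maximum plateau has constant intensity so it can never straddle an
# intensity edge, and speckle plateaus are the only failure mode; (2)
# shrink the survivors with a small erosion so markers stay clear of the
# gradient crest. A maxima plateau extends to the very edge of its
# structure, and imposing minima on un-eroded markers deletes the inner
# half of the edge's gradient band, which systematically drags the far
# side of the crest into the marker's basin (a one-pixel dilation bias of
# every basin grown from a plateau marker). Components the erosion would
# remove entirely are kept un-eroded.
clean_markers <- function(mask, se, connectivity, min_area) {
  comp <- label_components(mask, connectivity)
  if (max(comp) == 0) return(mask)
  sizes <- tabulate(comp[comp > 0], nbins = max(comp))
  keep <- which(sizes >= min_area)
  mask <- matrix(comp %in% keep, nrow(mask), ncol(mask))
  # radius-2 closing seals pinhole gaps the enhancement leaves inside a
  # plateau (erosion would otherwise shatter the marker), then the
  # radius-2 erosion pulls the marker off the gradient crest; the closing
  # radius is kept at the erosion radius so any outward bump it creates
  # is shaved back off
  closed <- erode(dilate(mask * 1, se_disk(2)), se_disk(2)) > 0
  eroded <- erode(closed * 1, se_disk(2)) > 0
  # confine the marker to the original plateau: closing may have bridged a
  # thin neighboring structure, and even one leaked pixel floods that
  # structure from the wrong seed; a plateau is constant-valued, so the
  # intersection can never straddle an intensity edge
  eroded <- eroded & mask
  for (k in keep)
    if (!any(eroded[comp == k])) eroded[comp == k] <- TRUE
  eroded
}

#' Run the full segmentation pipeline
#'
#' Executes, in order: load -> grayscale conversion -> optional polarity
#' complement -> HMR enhancement -> Sobel gradient magnitude -> marker
#' extraction (regional maxima of the enhanced image after shallow-maxima
#' merging, consolidated by an area floor, a pinhole-sealing closing and a
#' small erosion, and confined to their source plateaus) ->
#' marker-controlled (or unmarked) watershed of the gradient surface ->
#' overlay -> per-basin ROI statistics measured on the ORIGINAL intensities.
#'
#' @param input a height x width x 3 8-bit array, an 8-bit grayscale
#'   matrix, a PNG/TIFF file path, or a \code{\link{phantom_spec}} (the
#'   phantom is generated with the config seed substituted).
#' @param config a \code{\link{pipeline_config}}.
#' @param baseline optional \code{\link{roi_stats}} panel from an earlier
#'   measurement; when supplied, a \code{\link{severity_report}} against
#'   the largest basin's panel is included in the result.
#' @param out_dir optional directory; when given, every stage image, the
#'   label map (16-bit TIFF + run-length CSV), the overlay, the statistics
#'   table (CSV and JSON) and a JSON echo of the configuration are written
#'   there with fixed file names.
#' @return An object of class \code{"hmrseg_result"}: list with
#'   \code{labels}, \code{stats} (per-basin data.frame), \code{stages}
#'   (named list of intermediate images), \code{markers}, \code{overlay},
#'   \code{config}, \code{severity} (or NULL), and \code{paths} (written
#'   files, when \code{out_dir} was given).
#' @export
run_pipeline <- function(input, config = pipeline_config(),
                         baseline = NULL, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop("'config' must be a pipeline_config")
  ground_truth <- NULL
  if (inherits(input, "phantom_spec")) {
    input$seed <- config$seed
    ph <- if (input$kind == "artery") generate_artery(input)
          else generate_retina(input)
    ground_truth <- ph$labels
    input <- ph$image
  } else if (is.character(input)) {
    input <- read_image(input)
  }
  if (is.matrix(input)) {
    assert_gray8(input)
    original <- gray_to_rgb(input)
    gray <- input
  } else {
    assert_rgb(input)
    original <- input
    gray <- rgb_to_gray(input)
  }
  work <- if (config$polarity == "invert") complement(gray) else gray
  se <- default_se(work, config$se_shape, config$se_radius)
  enhanced <- hmr_enhance(work, se, config$connectivity)
  surface <- sobel_gradient_magnitude(
    if (config$legacy_order) work else enhanced)

  markers <- NULL
  marker_labels <- NULL
  if (config$marker_mode == "maxima") {
    # marker extraction always uses 8-connectivity: an intensity plateau
    # is one structure however its pixels touch, so one structure yields
    # one marker even when the flood itself runs 4-connected
    marker_surface <- enhanced
    if (config$marker_merge_depth > 0)
      marker_surface <- reconstruct_by_dilation(
        pmax(enhanced - config$marker_merge_depth, 0), enhanced, 8)
    raw_markers <- regional_maxima(marker_surface, 8)
    min_area <- if (is.null(config$marker_min_area))
      sum(se$footprint) else config$marker_min_area
    markers <- clean_markers(raw_markers, se, 8, min_area)
    if (!any(markers))
      stop("marker extraction produced no markers; ",
           "check polarity or use marker_mode = 'none'")
    marker_labels <- label_components(markers, 8)
  } else if (config$marker_mode == "mask") {
    markers <- config$marker_mask
    if (!identical(dim(markers), dim(gray)))
      stop("'marker_mask' shape does not match the input image")
    if (!any(markers))
      stop("external marker mask is empty")
  }
  labels <- if (is.null(markers))
    watershed_flood(surface, config$connectivity)
  else
    marker_watershed(surface, markers, config$connectivity,
                     marker_labels = marker_labels)

  overlay <- superimpose(original, labels, config$line_color)
  stats <- basin_stats(original, labels)
  severity <- NULL
  if (!is.null(baseline)) {
    ks <- sort(unique(labels[labels > 0]))
    areas <- vapply(ks, function(k) sum(labels == k), numeric(1))
    principal <- ks[which.max(areas)]
    severity <- severity_report(baseline,
                                roi_stats(original, labels == principal))
  }
  stages <- list(gray = gray, enhanced = enhanced, gradient = surface)
  res <- structure(list(labels = labels, stats = stats, stages = stages,
                        markers = markers, overlay = overlay,
                        config = config, severity = severity,
                        ground_truth = ground_truth, paths = NULL),
                   class = "hmrseg_result")
  if (!is.null(out_dir)) res$paths <- write_trace(res, out_dir)
  res
}

write_trace <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    gray = write_image(res$stages$gray, p("stage_gray.png")),
    enhanced = write_image(res$stages$enhanced, p("stage_enhanced.png")),
    gradient = write_image(res$stages$gradient, p("stage_gradient.png")),
    labels_tif = write_labels(res$labels, p("labels.tif")),
    labels_csv = write_labels(res$labels, p("labels.csv")),
    overlay = write_image(res$overlay, p("overlay.png")),
    stats_csv = write_stats(res$stats, p("stats.csv")),
    stats_json = write_stats(res$stats, p("stats.json")))
  if (!is.null(res$markers))
    paths["markers"] <- write_image(res$markers * 255, p("stage_markers.png"))
  cfg <- res$config
  cfg$marker_mask <- NULL
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       p("config.json"), auto_unbox = TRUE, digits = NA)
  paths["config"] <- p("config.json")
  paths
}

#' @export
print.hmrseg_result <- function(x, ...) {
  nb <- max(x$labels)
  cat(sprintf("hmrseg result: %d basin%s, %d watershed-line pixels (%dx%d)\n",
              nb, if (nb == 1) "" else "s", sum(x$labels == 0),
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}
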