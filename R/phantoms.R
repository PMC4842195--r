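# Synthetic phantoms with exact ground truth: concentric-ring artery
# cross-sections with a controllable lumen occlusion, and retinal
# fundus-like discs with bright exudate and dark hemorrhage blobs.

#' Ground-truth label codes for phantom images
#'
#' Artery phantoms label background 1, adventitia 2, media 3, intima 4,
#' open lumen 5 and plaque 6. Retina phantoms label the dark surround 1 and
#' the fundus disc 2; each exudate and hemorrhage lesion then gets its own
#' label (exudates first), recorded in the \code{exudate_labels} /
#' \code{hemorrhage_labels} attributes of the returned label matrix.
#'
#' @format Named integer vector.
#' @export
ARTERY_LABELS <- c(background = 1L, adventitia = 2L, media = 3L,
                   intima = 4L, lumen = 5L, plaque = 6L)

#' Phantom specification
#'
#' Parametric description of a synthetic test image. Defaults describe a
#' 256-pixel phantom with layer radii and intensities chosen so that every
#' tissue interface carries a clear intensity edge: artery palette
#' background 20, adventitia 200, media 120, intima 90, lumen 250,
#' plaque 140 (8-bit units).
#'
#' @param kind \code{"artery"} or \code{"retina"}.
#' @param size image side length in pixels.
#' @param layer_radii artery only: strictly increasing fractions of the
#'   half-size for lumen, intima, media, adventitia outer radii, all <= 1.
#' @param occlusion_fraction artery only: fraction of the lumen disc filled
#'   with plaque, in \code{[0, 1]}.
#' @param lesion_counts retina only: named vector
#'   \code{c(exudates = , hemorrhages = )}.
#' @param palette named per-structure 8-bit base intensities; defaults per
#'   kind.
#' @param noise_sd additive Gaussian noise standard deviation, intensity
#'   units (>= 0).
#' @param seed integer seed; phantom generation is fully deterministic in
#'   the spec.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(kind = c("artery", "retina"),
                         size = 256L,
                         layer_radii = c(lumen = 0.30, intima = 0.42,
                                         media = 0.58, adventitia = 0.78),
                         occlusion_fraction = 0,
                         lesion_counts = c(exudates = 5L, hemorrhages = 3L),
                         palette = NULL,
                         noise_sd = 5,
                         seed = 1L) {
  kind <- match.arg(kind)
  if (!(length(size) == 1L && size >= 32 && size == round(size)))
    stop("'size' must be an integer >= 32")
  if (kind == "artery") {
    if (length(layer_radii) != 4L || any(diff(layer_radii) <= 0) ||
        any(layer_radii <= 0) || any(layer_radii > 1))
      stop("'layer_radii' must be 4 strictly increasing fractions in (0, 1]")
    if (!(occlusion_fraction >= 0 && occlusion_fraction <= 1))
      stop("'occlusion_fraction' must be in [0, 1]")
    if (is.null(palette))
      palette <- c(background = 20, adventitia = 200, media = 120,
                   intima = 90, lumen = 250, plaque = 140)
  } else {
    if (length(lesion_counts) != 2L || any(lesion_counts < 0))
      stop("'lesion_counts' must be two non-negative counts")
    if (is.null(palette))
      palette <- c(surround = 10, disc_center = 190, disc_edge = 120,
                   exudate = 240, hemorrhage = 40)
  }
  if (!(length(noise_sd) == 1L && noise_sd >= 0))
    stop("'noise_sd' must be >= 0")
  structure(list(kind = kind, size = as.integer(size),
                 layer_radii = layer_radii,
                 occlusion_fraction = occlusion_fraction,
                 lesion_counts = lesion_counts,
                 palette = palette, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run `expr` under the spec's seed without disturbing the caller's RNG
with_phantom_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# per-channel tint applied to the gray palette so phantoms are RGB like the
# photographs they stand in for; channel noise is independent
tint_and_noise <- function(base, tint, noise_sd) {
  img <- array(0, dim = c(dim(base), 3L))
  for (ch in 1:3) {
    plane <- base * tint[ch]
    if (noise_sd > 0)
      plane <- plane + rnorm(length(plane), sd = noise_sd)
    img[, , ch] <- clip8(plane)
  }
  img
}

#' Generate an artery cross-section phantom
#'
#' Renders concentric discs (lumen, intima, media, adventitia) on a dark
#' background, then fills \code{occlusion_fraction} of the lumen disc with
#' a plaque region accreted from the intima wall inward around a random
#' angular position — an eccentric, wall-hugging occlusion. Additive
#' clipped Gaussian noise is applied per channel. The output is fully
#' determined by the spec (same seed, same bits).
#'
#' @param spec a \code{\link{phantom_spec}} with \code{kind = "artery"}.
#' @return A list with \code{image} (height x width x 3 array of 8-bit
#'   values) and \code{labels} (integer ground-truth matrix, see
#'   \code{\link{ARTERY_LABELS}}).
#' @export
generate_artery <- function(spec) {
  if (!inherits(spec, "phantom_spec") || spec$kind != "artery")
    stop("'spec' must be a phantom_spec of kind 'artery'")
  n <- spec$size
  half <- n / 2
  cx <- (n + 1) / 2
  ix <- seq_len(n) - cx
  r <- sqrt(outer(ix^2, ix^2, "+"))   # radial distance, pixels
  rad <- spec$layer_radii * half

  labels <- matrix(ARTERY_LABELS[["background"]], n, n)
  labels[r <= rad[4]] <- ARTERY_LABELS[["adventitia"]]
  labels[r <= rad[3]] <- ARTERY_LABELS[["media"]]
  labels[r <= rad[2]] <- ARTERY_LABELS[["intima"]]
  labels[r <= rad[1]] <- ARTERY_LABELS[["lumen"]]

  with_phantom_seed(spec$seed, {
    if (spec$occlusion_fraction > 0) {
      lumen_px <- which(labels == ARTERY_LABELS[["lumen"]])
      target <- round(spec$occlusion_fraction * length(lumen_px))
      if (target > 0) {
        theta0 <- runif(1, -pi, pi)
        row_i <- (lumen_px - 1L) %% n + 1L
        col_j <- (lumen_px - 1L) %/% n + 1L
        ang <- atan2(col_j - cx, row_i - cx)
        dang <- abs(((ang - theta0 + pi) %% (2 * pi)) - pi)
        depth <- rad[1] - r[lumen_px]          # distance in from the wall
        pot <- depth + 0.6 * rad[1] * dang     # accretion potential
        plaque <- lumen_px[order(pot)[seq_len(target)]]
        labels[plaque] <- ARTERY_LABELS[["plaque"]]
      }
    }
    base <- matrix(spec$palette[["background"]], n, n)
    for (nm in c("adventitia", "media", "intima", "lumen", "plaque"))
      base[labels == ARTERY_LABELS[[nm]]] <- spec$palette[[nm]]
    image <- tint_and_noise(base, c(1.0, 0.9, 0.8), spec$noise_sd)
    list(image = image, labels = labels)
  })
}

#' Generate a retinal fundus-like phantom
#'
#' Renders a bright fundus disc with quadratic radial intensity falloff on
#' a dark surround, then places the requested numbers of compact bright
#' exudate blobs and dark hemorrhage blobs at seeded non-overlapping
#' positions inside the disc. Placement retries are bounded; lesion loads
#' that cannot be placed without overlap raise an error.
#'
#' @param spec a \code{\link{phantom_spec}} with \code{kind = "retina"}.
#' @return A list with \code{image} (8-bit RGB array) and \code{labels}
#'   (integer matrix: 1 surround, 2 disc, one label per lesion; exudate and
#'   hemorrhage label ids are in the matrix attributes
#'   \code{exudate_labels} / \code{hemorrhage_labels}).
#' @export
generate_retina <- function(spec) {
  if (!inherits(spec, "phantom_spec") || spec$kind != "retina")
    stop("'spec' must be a phantom_spec of kind 'retina'")
  n <- spec$size
  cx <- (n + 1) / 2
  ix <- seq_len(n) - cx
  r <- sqrt(outer(ix^2, ix^2, "+"))
  disc_r <- 0.92 * n / 2
  pal <- spec$palette

  with_phantom_seed(spec$seed, {
    base <- matrix(pal[["surround"]], n, n)
    inside <- r <= disc_r
    fall <- pal[["disc_center"]] -
      (pal[["disc_center"]] - pal[["disc_edge"]]) * (r / disc_r)^2
    base[inside] <- fall[inside]
    labels <- matrix(1L, n, n)
    labels[inside] <- 2L

    n_ex <- as.integer(spec$lesion_counts[[1]])
    n_he <- as.integer(spec$lesion_counts[[2]])
    taken <- matrix(FALSE, n, n)   # shared by both lesion families
    place <- function(count, rmin, rmax) {
      blobs <- vector("list", count)
      if (count == 0) return(blobs)
      for (b in seq_len(count)) {
        ok <- FALSE
        for (try in seq_len(200)) {
          rr <- runif(1, rmin, rmax)
          ang <- runif(1, -pi, pi)
          rho <- runif(1, 0, 0.70 * disc_r - rr)
          bi <- cx + rho * cos(ang)
          bj <- cx + rho * sin(ang)
          blob <- (outer((seq_len(n) - bi)^2, (seq_len(n) - bj)^2, "+")
                   <= rr^2)
          # keep lesions separated by a clear band of background
          grown <- (outer((seq_len(n) - bi)^2, (seq_len(n) - bj)^2, "+")
                    <= (rr + 4)^2)
          if (!any(grown & taken)) {
            taken <<- taken | grown
            blobs[[b]] <- blob
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop("could not place all lesions without overlap; ",
               "reduce the lesion counts or enlarge the phantom")
      }
      blobs
    }
    ex <- place(n_ex, 7, 10)
    he <- place(n_he, 5, 9)
    lab_id <- 2L
    ex_ids <- integer(0)
    for (b in seq_along(ex)) {
      lab_id <- lab_id + 1L
      ex_ids <- c(ex_ids, lab_id)
      labels[ex[[b]]] <- lab_id
      base[ex[[b]]] <- pal[["exudate"]]
    }
    he_ids <- integer(0)
    for (b in seq_along(he)) {
      lab_id <- lab_id + 1L
      he_ids <- c(he_ids, lab_id)
      labels[he[[b]]] <- lab_id
      base[he[[b]]] <- pal[["hemorrhage"]]
    }
    attr(labels, "exudate_labels") <- ex_ids
    attr(labels, "hemorrhage_labels") <- he_ids
    image <- tint_and_noise(base, c(1.0, 0.62, 0.45), spec$noise_sd)
    list(image = image, labels = labels)
  })
}
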