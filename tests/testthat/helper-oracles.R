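# Brute-force reference implementations, kept deliberately independent of
# the package's compiled kernels: plain double loops and literal
# definition-chasing, for use as oracles in the equivalence tests.

# in-bounds neighbor offsets for a connectivity
neighbor_offsets <- function(connectivity) {
  if (connectivity == 4)
    list(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  else
    list(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
         dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
}

# min/max filter by explicit double loop over the footprint
oracle_minmax <- function(img, fp, oi, oj, take_max) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  fidx <- which(fp, arr.ind = TRUE)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- c()
    for (m in seq_len(nrow(fidx))) {
      ni <- i + fidx[m, 1] - oi
      nj <- j + fidx[m, 2] - oj
      if (ni >= 1 && ni <= h && nj >= 1 && nj <= w)
        vals <- c(vals, img[ni, nj])
    }
    out[i, j] <- if (take_max) max(vals) else min(vals)
  }
  out
}

oracle_erode <- function(img, se)
  oracle_minmax(img, se$footprint, se$origin[1], se$origin[2], FALSE)

oracle_dilate <- function(img, se) {
  fp <- se$footprint[rev(seq_len(nrow(se$footprint))),
                     rev(seq_len(ncol(se$footprint))), drop = FALSE]
  oracle_minmax(img, fp, se$origin[1], se$origin[2], TRUE)
}

# one unit geodesic dilation: dilate by the unit connectivity
# neighborhood, then clip to the mask
unit_geodesic_dilation <- function(img, mask, connectivity) {
  h <- nrow(img); w <- ncol(img)
  off <- neighbor_offsets(connectivity)
  out <- img
  for (m in seq_along(off$di)) {
    sh <- matrix(-Inf, h, w)
    si <- seq_len(h) - off$di[m]
    sj <- seq_len(w) - off$dj[m]
    ok_i <- si >= 1 & si <= h
    ok_j <- sj >= 1 & sj <= w
    sh[ok_i, ok_j] <- img[si[ok_i], sj[ok_j]]
    out <- pmax(out, sh)
  }
  pmin(out, mask)
}

# iterate unit geodesic dilations to the fixed point — the definitional
# reconstruction-by-dilation
oracle_reconstruct <- function(marker, mask, connectivity = 8) {
  cur <- pmin(marker, mask)
  repeat {
    nxt <- unit_geodesic_dilation(cur, mask, connectivity)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

# enumerate constant-intensity plateaus by flood fill and test every
# external neighbor — the definitional regional maxima
oracle_regional_maxima <- function(img, connectivity = 8) {
  h <- nrow(img); w <- ncol(img)
  off <- neighbor_offsets(connectivity)
  seen <- matrix(FALSE, h, w)
  out <- matrix(FALSE, h, w)
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    if (seen[i0, j0]) next
    v <- img[i0, j0]
    plateau <- matrix(c(i0, j0), 1, 2)
    seen[i0, j0] <- TRUE
    is_max <- TRUE
    head <- 1
    while (head <= nrow(plateau)) {
      i <- plateau[head, 1]; j <- plateau[head, 2]; head <- head + 1
      for (m in seq_along(off$di)) {
        ni <- i + off$di[m]; nj <- j + off$dj[m]
        if (ni < 1 || ni > h || nj < 1 || nj > w) next
        if (img[ni, nj] == v) {
          if (!seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            plateau <- rbind(plateau, c(ni, nj))
          }
        } else if (img[ni, nj] > v) is_max <- FALSE
      }
    }
    if (is_max) out[plateau] <- TRUE
  }
  out
}

# Steepest-descent drainage watershed, literal set semantics: every pixel
# carries the set of regional minima its water can reach by always
# stepping to a minimum-valued lower neighbor (all tied steepest routes
# followed); plateau pixels take the union over their geodesically
# nearest draining exits. |set| > 1 -> watershed line (0). Minima are
# numbered by raster order of each minimum plateau's first pixel, to
# match the package's labeling contract.
oracle_watershed <- function(surface, connectivity = 8) {
  h <- nrow(surface); w <- ncol(surface); n <- h * w
  off <- neighbor_offsets(connectivity)
  nb_of <- function(p) {
    i <- (p - 1) %% h + 1; j <- (p - 1) %/% h + 1
    ni <- i + off$di; nj <- j + off$dj
    ok <- ni >= 1 & ni <= h & nj >= 1 & nj <= w
    (nj[ok] - 1) * h + ni[ok]
  }
  nbs <- lapply(seq_len(n), nb_of)
  sets <- vector("list", n)
  minima_first <- integer(0)
  for (lev in sort(unique(as.vector(surface)))) {
    px <- which(surface == lev)
    remaining <- px
    while (length(remaining)) {
      # flood-fill one plateau
      plat <- remaining[1]
      frontier <- plat
      while (length(frontier)) {
        nxt <- unique(unlist(nbs[frontier]))
        nxt <- nxt[surface[nxt] == lev & !(nxt %in% plat)]
        plat <- c(plat, nxt)
        frontier <- nxt
      }
      remaining <- setdiff(remaining, plat)
      # exits drain via their minimum-valued lower neighbors
      exit_sets <- list(); exit_px <- integer(0)
      for (p in plat) {
        lower <- nbs[[p]][surface[nbs[[p]]] < lev]
        if (!length(lower)) next
        steep <- lower[surface[lower] == min(surface[lower])]
        exit_px <- c(exit_px, p)
        exit_sets[[length(exit_px)]] <-
          sort(unique(unlist(sets[steep])))
      }
      if (!length(exit_px)) {
        # regional minimum: new basin id, assigned after numbering pass
        minima_first <- c(minima_first, min(plat))
        for (p in plat) sets[[p]] <- -length(minima_first) # placeholder id
      } else {
        # geodesic distance from every plateau pixel to every exit
        dist <- matrix(Inf, length(plat), length(exit_px))
        rownames(dist) <- as.character(plat)
        for (e in seq_along(exit_px)) {
          d <- 0; cur <- exit_px[e]
          dst <- setNames(rep(Inf, length(plat)), as.character(plat))
          dst[as.character(cur)] <- 0
          while (length(cur)) {
            nxt <- unique(unlist(nbs[cur]))
            nxt <- nxt[nxt %in% plat]
            nxt <- nxt[is.infinite(dst[as.character(nxt)])]
            d <- d + 1
            dst[as.character(nxt)] <- d
            cur <- nxt
          }
          dist[, e] <- dst
        }
        for (r in seq_along(plat)) {
          dmin <- min(dist[r, ])
          near <- which(dist[r, ] == dmin)
          sets[[plat[r]]] <- sort(unique(unlist(exit_sets[near])))
        }
      }
    }
  }
  # number minima by raster order of their plateau's first pixel
  ord <- order(minima_first)
  rank_of <- integer(length(ord)); rank_of[ord] <- seq_along(ord)
  lab <- matrix(0L, h, w)
  for (p in seq_len(n)) {
    s <- sets[[p]]
    s <- unique(ifelse(s < 0, rank_of[-s], s))
    # re-resolve placeholder ids recorded before numbering
    lab[p] <- if (length(s) == 1) s else 0L
  }
  lab
}

# seeded random 8-bit test image
rand_img8 <- function(h, w, vals = 0:255)
  matrix(sample(vals, h * w, replace = TRUE), h, w)
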