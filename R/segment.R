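#' Segmentation configuration
#'
#' @param h dome height: either an absolute intensity (`h_mode = "absolute"`)
#'   or a fraction of `max - median` of the map (`h_mode = "fraction"`,
#'   default 0.25).
#' @param h_mode `"fraction"` or `"absolute"`.
#' @param connectivity pixel connectivity for reconstruction and labelling
#'   (8, default, or 4).
#' @param radius structuring-element radius of the opening (grid units).
#' @param element `"cross"` (city-block disc, default) or `"square"`.
#' @param seed_point optional `c(row, col)` used to select the region of
#'   interest among the segmented components.
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(h = 0.25, h_mode = c("fraction", "absolute"),
                                connectivity = 8, radius = 1,
                                element = c("cross", "square"),
                                seed_point = NULL) {
  check_scalar_positive(h, "h")
  if (!connectivity %in% c(4, 8)) {
    stop_hdemg("invalid_argument", "`connectivity` must be 4 or 8")
  }
  if (radius < 1) stop_hdemg("invalid_argument", "`radius` must be >= 1")
  structure(list(h = h, h_mode = match.arg(h_mode),
                 connectivity = as.integer(connectivity),
                 radius = as.integer(radius), element = match.arg(element),
                 seed_point = seed_point),
            class = "segmentation_config")
}

# one geodesic dilation step: neighbourhood max capped by the mask
dilate_step <- function(m, connectivity) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  sh <- function(dr, dc) p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  out <- pmax(m, sh(-1L, 0L), sh(1L, 0L), sh(0L, -1L), sh(0L, 1L))
  if (connectivity == 8L) {
    out <- pmax(out, sh(-1L, -1L), sh(-1L, 1L), sh(1L, -1L), sh(1L, 1L))
  }
  out
}

#' Grayscale morphological reconstruction (geodesic dilation to stability)
#'
#' Iterates "dilate the marker by the connectivity neighbourhood, then take
#' the pointwise minimum with the mask" until a fixpoint: the reconstruction
#' of `mask` from `marker`. The result r satisfies `marker <= r <= mask`.
#'
#' @param marker,mask numeric matrices with `marker <= mask` elementwise.
#' @param connectivity 8 (default) or 4.
#' @return the reconstructed matrix.
#' @export
geodesic_reconstruct <- function(marker, mask, connectivity = 8) {
  if (!all(dim(marker) == dim(mask))) {
    stop_hdemg("invalid_argument", "marker and mask shapes differ")
  }
  if (any(marker > mask)) {
    stop_hdemg("invalid_argument", "marker must not exceed the mask anywhere")
  }
  cur <- marker
  repeat {
    nxt <- pmin(dilate_step(cur, connectivity), mask)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

#' h-dome transform
#'
#' `D_h(I) = I - reconstruct(I - h under I)`: keeps every dome of height at
#' least `h` above its surroundings — including domes containing several
#' local maxima — with values in `[0, h]`.
#'
#' @param I numeric matrix (activation map intensity).
#' @param h dome height (> 0, absolute intensity units).
#' @param connectivity 8 (default) or 4.
#' @return the dome image, same shape as `I`.
#' @export
h_dome <- function(I, h, connectivity = 8) {
  check_scalar_positive(h, "h")
  I - geodesic_reconstruct(I - h, I, connectivity)
}

se_offsets <- function(radius, element) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  if (element == "cross") d <- d[abs(d$dr) + abs(d$dc) <= radius, ]
  d
}

# min/max filter over the structuring element, restricted to the grid
se_filter <- function(m, offsets, op) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- max(abs(offsets$dr), abs(offsets$dc))
  fill <- if (identical(op, pmin)) Inf else -Inf
  p <- matrix(fill, nr + 2L * pad, nc + 2L * pad)
  p[pad + (1:nr), pad + (1:nc)] <- m
  out <- matrix(fill, nr, nc)
  for (i in seq_len(nrow(offsets))) {
    out <- op(out, p[pad + (1:nr) + offsets$dr[i], pad + (1:nc) + offsets$dc[i]])
  }
  out
}

#' Grayscale opening with a disc structuring element
#'
#' Erosion followed by dilation with a disc of the given radius (the
#' city-block "cross" of 5 pixels for radius 1 by default). Removes isolated
#' peaks smaller in area than the element; anti-extensive and idempotent.
#'
#' @param D numeric matrix (dome image).
#' @param radius element radius in grid units (>= 1).
#' @param element `"cross"` (default) or `"square"`.
#' @return the opened matrix.
#' @export
open_disc <- function(D, radius = 1, element = c("cross", "square")) {
  element <- match.arg(element)
  if (radius < 1) stop_hdemg("invalid_argument", "`radius` must be >= 1")
  off <- se_offsets(radius, element)
  er <- se_filter(D, off, pmin)
  se_filter(er, off, pmax)
}

label_components <- function(support, connectivity = 8) {
  nr <- nrow(support); nc <- ncol(support)
  labels <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8L) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1), dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  lab <- 0L
  for (start in which(support & labels == 0L)) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      r <- (cur - 1L) %% nr + 1L; c <- (cur - 1L) %/% nr + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb[k, 1L]; cc <- c + nb[k, 2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            support[rr, cc] && labels[rr, cc] == 0L) {
          labels[rr, cc] <- lab
          queue <- c(queue, (cc - 1L) * nr + rr)
        }
      }
    }
  }
  labels
}

#' Segment active regions of an activation map
#'
#' Applies the h-dome transform followed by a grayscale opening, then labels
#' the connected components of the strictly positive dome support, ordered
#' by decreasing peak dome height. When a seed point is given the selected
#' region is the component containing (or nearest to) the seed, mirroring
#' the exclusion of regions belonging to neighbouring muscles; otherwise the
#' highest-peak component is selected.
#'
#' @param map an [compute_map()] result (or a plain numeric matrix).
#' @param config a [segmentation_config()].
#' @return an object of class `segmented_map`: dome image `dome`, integer
#'   `labels` grid (0 = background), `selected` region id, per-region table
#'   `regions` (id, area, peak, centroid), the `h` actually used, and the
#'   source map.
#' @export
extract_active_regions <- function(map, config = segmentation_config()) {
  I <- if (inherits(map, "activation_map")) map$intensity else map
  h <- if (config$h_mode == "fraction") {
    config$h * (max(I) - stats::median(I))
  } else {
    config$h
  }
  if (!is.finite(h) || h <= 0) {
    stop_hdemg("no_region_error", "map has no intensity range to segment")
  }
  # a dome of height h needs at least that much relief; below it the
  # transform leaves only a flat finite-support residue ("flat map" case)
  if (max(I) - min(I) <= h) {
    stop_hdemg("no_region_error", "map relief is below the dome height h")
  }
  dome <- h_dome(I, h, config$connectivity)
  dome <- open_disc(dome, config$radius, config$element)
  support <- dome > 0
  if (!any(support)) {
    stop_hdemg("no_region_error", "no active region above the dome height")
  }
  labels0 <- label_components(support, config$connectivity)
  peaks <- vapply(seq_len(max(labels0)), function(l) max(dome[labels0 == l]),
                  numeric(1))
  ord <- order(peaks, decreasing = TRUE)
  labels <- matrix(0L, nrow(I), ncol(I))
  for (newl in seq_along(ord)) labels[labels0 == ord[newl]] <- newl
  regions <- do.call(rbind, lapply(seq_along(ord), function(l) {
    px <- which(labels == l, arr.ind = TRUE)
    data.frame(id = l, area = nrow(px), peak = max(dome[labels == l]),
               centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]))
  }))
  selected <- 1L
  if (!is.null(config$seed_point)) {
    sr <- config$seed_point[1]; sc <- config$seed_point[2]
    if (labels[sr, sc] > 0L) {
      selected <- labels[sr, sc]
    } else {
      px <- which(labels > 0L, arr.ind = TRUE)
      d2 <- (px[, 1] - sr)^2 + (px[, 2] - sc)^2
      selected <- labels[px[which.min(d2), , drop = FALSE]]
    }
  }
  structure(list(dome = dome, labels = labels, selected = as.integer(selected),
                 regions = regions, h = h, config = config,
                 map = if (inherits(map, "activation_map")) map else NULL),
            class = "segmented_map")
}

#' @export
print.segmented_map <- function(x, ...) {
  cat(sprintf("<segmented_map> %d region(s), selected #%d (area %d), h = %.4g\n",
              nrow(x$regions), x$selected,
              x$regions$area[x$regions$id == x$selected], x$h))
  invisible(x)
}
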