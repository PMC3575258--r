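#' Normalise map coordinates to limb-relative units
#'
#' Maps electrode coordinates to fractions of the limb segment: x becomes
#' `(col - origin_col) * pitch / circumference` and y becomes
#' `(row - origin_row) * pitch / segment_length`, with the anatomical
#' reference electrode at (0, 0). Intensities are untouched.
#'
#' @param map an [compute_map()] result.
#' @param grid an [electrode_grid()] carrying `circumference_mm` and
#'   `segment_length_mm`; defaults to the map's own grid.
#' @return an object of class `normalized_map` with `intensity`, `x`, `y`.
#' @export
normalize_map_coords <- function(map, grid = map$grid) {
  if (is.na(grid$circumference_mm) || is.na(grid$segment_length_mm) ||
      grid$circumference_mm <= 0 || grid$segment_length_mm <= 0) {
    stop_hdemg("invalid_argument",
               "grid must carry positive circumference_mm and segment_length_mm")
  }
  x <- (seq_len(grid$n_cols) - grid$origin_col) * grid$pitch_mm / grid$circumference_mm
  y <- (seq_len(grid$n_rows) - grid$origin_row) * grid$pitch_mm / grid$segment_length_mm
  structure(list(intensity = map$intensity, x = x, y = y, grid = grid),
            class = "normalized_map")
}

#' Resample a normalised map onto a common grid
#'
#' Separable cubic-spline interpolation along x then y onto the target
#' coordinate vectors, which must lie within the source coordinate range (no
#' extrapolation).
#'
#' @param nmap a [normalize_map_coords()] result.
#' @param x_out,y_out strictly monotone target coordinates.
#' @return a `normalized_map` on the target coordinates.
#' @export
resample_common_grid <- function(nmap, x_out, y_out) {
  if (min(x_out) < min(nmap$x) - 1e-12 || max(x_out) > max(nmap$x) + 1e-12 ||
      min(y_out) < min(nmap$y) - 1e-12 || max(y_out) > max(nmap$y) + 1e-12) {
    stop_hdemg("out_of_range", "target coordinates extend beyond the source map")
  }
  I <- nmap$intensity
  tmp <- t(apply(I, 1, function(rowv)
    stats::splinefun(nmap$x, rowv, method = "fmm")(x_out)))
  out <- apply(tmp, 2, function(colv)
    stats::splinefun(nmap$y, colv, method = "fmm")(y_out))
  if (!is.matrix(out)) out <- matrix(out, nrow = length(y_out))
  structure(list(intensity = out, x = as.numeric(x_out), y = as.numeric(y_out),
                 grid = nmap$grid),
            class = "normalized_map")
}

#' Common-grid coordinates for a set of normalised maps
#'
#' The shared grid spans the intersection of the subjects' coordinate ranges
#' at `factor` times the densest source resolution in each axis, so no map
#' is extrapolated and peaks are preserved.
#'
#' @param nmaps list of `normalized_map`s.
#' @param factor oversampling factor (default 2).
#' @return list with `x` and `y` coordinate vectors.
#' @export
common_grid_coords <- function(nmaps, factor = 2) {
  lo_x <- max(vapply(nmaps, function(m) min(m$x), numeric(1)))
  hi_x <- min(vapply(nmaps, function(m) max(m$x), numeric(1)))
  lo_y <- max(vapply(nmaps, function(m) min(m$y), numeric(1)))
  hi_y <- min(vapply(nmaps, function(m) max(m$y), numeric(1)))
  if (lo_x >= hi_x || lo_y >= hi_y) {
    stop_hdemg("invalid_argument", "maps do not share a coordinate range")
  }
  nx <- factor * max(vapply(nmaps, function(m) length(m$x), integer(1)))
  ny <- factor * max(vapply(nmaps, function(m) length(m$y), integer(1)))
  list(x = seq(lo_x, hi_x, length.out = nx), y = seq(lo_y, hi_y, length.out = ny))
}

#' Average maps across subjects with a variability map
#'
#' Pixelwise mean of the maps plus the inter-subject variability map:
#' standard deviation (n-1) divided by the mean-map intensity (undefined
#' where the mean is 0). The summary (mean, min, max of the variability over
#' the evaluated pixels) is the usual between-subject variability statistic.
#'
#' @param maps list of >= 2 `normalized_map`s on identical coordinates.
#' @param region optional logical matrix restricting the summary.
#' @return list with `mean_map` (a `normalized_map`), `variability` matrix
#'   and `summary` (`mean`, `min`, `max`).
#' @export
average_maps <- function(maps, region = NULL) {
  if (length(maps) < 2L) stop_hdemg("invalid_argument", "need at least 2 maps")
  x0 <- maps[[1]]$x; y0 <- maps[[1]]$y
  for (m in maps) {
    if (length(m$x) != length(x0) || length(m$y) != length(y0) ||
        max(abs(m$x - x0)) > 1e-9 || max(abs(m$y - y0)) > 1e-9) {
      stop_hdemg("invalid_argument", "maps are not on a common grid")
    }
  }
  arr <- simplify2array(lapply(maps, function(m) m$intensity))
  mean_map <- apply(arr, c(1, 2), mean)
  sd_map <- apply(arr, c(1, 2), stats::sd)
  variability <- ifelse(mean_map > 0, sd_map / mean_map, NA_real_)
  sel <- if (is.null(region)) !is.na(variability) else region & !is.na(variability)
  v <- variability[sel]
  list(mean_map = structure(list(intensity = mean_map, x = x0, y = y0,
                                 grid = maps[[1]]$grid),
                            class = "normalized_map"),
       variability = variability,
       summary = c(mean = mean(v), min = min(v), max = max(v)))
}

#' Project a segmented map onto one axis
#'
#' The projection at coordinate k is the maximum of the segmented dome image
#' over the orthogonal dimension, restricted to the selected region
#' (pixels outside it contribute 0).
#'
#' @param seg a [extract_active_regions()] result.
#' @param dim `"x"` (profile over columns) or `"y"` (profile over rows).
#' @param restrict use only the selected region (default `TRUE`).
#' @return an object of class `projection`: `dim`, `coords`, values `q`.
#' @export
project_map <- function(seg, dim = c("x", "y"), restrict = TRUE) {
  dim <- match.arg(dim)
  D <- seg$dome
  if (restrict) D <- D * (seg$labels == seg$selected)
  if (all(D <= 0)) stop_hdemg("no_region_error", "selected region is empty")
  q <- if (dim == "x") apply(D, 2, max) else apply(D, 1, max)
  q <- pmax(q, 0)
  coords <- if (!is.null(seg$map)) {
    if (dim == "x") seg$map$x_mm else seg$map$y_mm
  } else {
    seq_along(q)
  }
  structure(list(dim = dim, coords = as.numeric(coords), q = as.numeric(q)),
            class = "projection")
}

#' Median coordinate of a projection
#'
#' The coordinate splitting the area under the projection profile into two
#' equal halves. The cumulative mass is interpolated linearly between grid
#' coordinates (each coordinate's mass centred on it), giving a
#' sub-grid-resolution median.
#'
#' @param proj a [project_map()] result, or a list with `coords` and `q`.
#' @return the median coordinate (same units as `coords`).
#' @export
projection_median <- function(proj) {
  q <- proj$q; x <- proj$coords
  tot <- sum(q)
  if (!is.finite(tot) || tot <= 0) {
    stop_hdemg("undefined_median", "projection has zero total mass")
  }
  cum <- cumsum(q)
  centred <- cum - q / 2          # cumulative mass at each coordinate's centre
  half <- tot / 2
  k <- which(centred >= half)[1]
  if (is.na(k)) return(x[length(x)])
  if (k == 1L) return(x[1])
  x[k - 1L] + (half - centred[k - 1L]) / (centred[k] - centred[k - 1L]) *
    (x[k] - x[k - 1L])
}

#' Mean intensity over the selected segmented area
#'
#' The average RMS value of the source activation map over the pixels of the
#' selected region — the map-intensity feature used for task discrimination.
#'
#' @param map an [compute_map()] result (or matrix) on the same grid as
#'   `seg`.
#' @param seg a [extract_active_regions()] result.
#' @return scalar mean intensity.
#' @export
region_mean_intensity <- function(map, seg) {
  I <- if (inherits(map, "activation_map")) map$intensity else map
  sel <- seg$labels == seg$selected
  if (!any(sel)) stop_hdemg("no_region_error", "selected region is empty")
  mean(I[sel])
}

#' RMS of a single differential (bipolar) channel
#'
#' Subtracts two monopolar channels 10 mm apart along the fibre direction
#' (one row apart, same column, by convention) and computes the same
#' epoch-averaged RMS as the activation map for that signal.
#'
#' @param rec a [grid_recording()].
#' @param ch_a,ch_b `c(row, col)` positions of the two electrodes.
#' @param window_start first sample of the analysis window.
#' @param epoching an [epoching_spec()].
#' @param filt a [filter_spec()]; `NULL` skips filtering.
#' @return scalar RMS of the differential signal.
#' @export
bipolar_rms <- function(rec, ch_a, ch_b, window_start = 1L,
                        epoching = epoching_spec(), filt = filter_spec()) {
  if (identical(as.integer(ch_a), as.integer(ch_b))) {
    stop_hdemg("invalid_argument", "bipolar channels must differ")
  }
  ia <- grid_channel_index(rec$grid, ch_a[1], ch_a[2])
  ib <- grid_channel_index(rec$grid, ch_b[1], ch_b[2])
  fs <- rec$fs_hz
  len <- epoch_length_samples(epoching, fs)
  idx <- window_start - 1L + seq_len(epoching$n_epochs * len)
  if (window_start < 1L || max(idx) > ncol(rec$samples)) {
    stop_hdemg("length_error", "analysis window not covered by the recording")
  }
  d <- rec$samples[ia, idx] - rec$samples[ib, idx]
  if (!is.null(filt)) d <- bandpass_zero_phase(d, fs, filt)
  em <- matrix(d, nrow = len)
  mean(sqrt(colMeans(em^2)))
}
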