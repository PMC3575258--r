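# File formats: signals as delimited text (or flat float32 binary) plus a
# JSON sidecar describing the grid; maps as TSV + JSON; QC and feature
# tables as TSV/CSV. Grid indices are written 0-based in sidecars (row 0 =
# most proximal, col 0 = most lateral) and used 1-based inside R.

grid_to_sidecar <- function(grid, fs_hz, n_samples, format, units = "mV") {
  list(n_rows = grid$n_rows, n_cols = grid$n_cols, pitch_mm = grid$pitch_mm,
       origin_row = grid$origin_row - 1L, origin_col = grid$origin_col - 1L,
       circumference_mm = grid$circumference_mm,
       segment_length_mm = grid$segment_length_mm,
       fs_hz = fs_hz, n_samples = n_samples, format = format, units = units)
}

sidecar_to_grid <- function(sc) {
  electrode_grid(sc$n_rows, sc$n_cols, sc$pitch_mm,
                 origin_row = sc$origin_row + 1L, origin_col = sc$origin_col + 1L,
                 circumference_mm = sc$circumference_mm %||% NA_real_,
                 segment_length_mm = sc$segment_length_mm %||% NA_real_)
}

#' Write a grid recording to disk
#'
#' @param rec a [grid_recording()].
#' @param path signal file; the JSON sidecar is written next to it as
#'   `<path>.json`.
#' @param format `"tsv"` (tab-delimited text, one channel per row, full
#'   double precision) or `"f32"` (flat little-endian float32, channel-major).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("tsv", "f32")) {
  format <- match.arg(format)
  sc <- grid_to_sidecar(rec$grid, rec$fs_hz, ncol(rec$samples), format)
  jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  if (format == "tsv") {
    lines <- apply(rec$samples, 1, function(rw)
      paste(sprintf("%.17g", rw), collapse = "\t"))
    writeLines(lines, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(rec$samples)), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a grid recording from disk
#'
#' @param path signal file written by [write_recording()].
#' @param sidecar path of the JSON sidecar (default `<path>.json`).
#' @return a [grid_recording()].
#' @export
read_recording <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop_hdemg("format_error", sprintf("no such file: %s", path))
  if (!file.exists(sidecar)) stop_hdemg("format_error", sprintf("no sidecar: %s", sidecar))
  sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  grid <- sidecar_to_grid(sc)
  nch <- grid$n_rows * grid$n_cols
  if (identical(sc$format, "f32")) {
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = nch * sc$n_samples + 1L, size = 4L,
                    endian = "little")
    if (length(vals) != nch * sc$n_samples) {
      stop_hdemg("dimension_mismatch",
                 sprintf("file holds %d values but sidecar declares %d x %d",
                         length(vals), nch, sc$n_samples))
    }
    samples <- matrix(vals, nrow = nch, byrow = TRUE)
  } else {
    m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    if (nrow(m) != nch || ncol(m) != sc$n_samples) {
      stop_hdemg("dimension_mismatch",
                 sprintf("file is %d x %d but sidecar declares %d channels x %d samples",
                         nrow(m), ncol(m), nch, sc$n_samples))
    }
    samples <- m
  }
  grid_recording(samples, sc$fs_hz, grid)
}

#' Write / read an activation map (TSV matrix + JSON sidecar)
#'
#' @param map an [compute_map()] result or `normalized_map`.
#' @param path TSV file for the intensity matrix; coordinates and provenance
#'   go to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  x <- map$x_mm %||% map$x
  y <- map$y_mm %||% map$y
  meta <- list(x = x, y = y,
               units = "rms",
               interpolated = map$interpolated,
               n_rows = nrow(map$intensity), n_cols = ncol(map$intensity))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  lines <- apply(map$intensity, 1, function(rw)
    paste(sprintf("%.17g", rw), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop_hdemg("format_error", sprintf("no such file: %s", path))
  if (!file.exists(paste0(path, ".json"))) {
    stop_hdemg("format_error", sprintf("no sidecar: %s.json", path))
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != meta$n_rows || ncol(m) != meta$n_cols) {
    stop_hdemg("dimension_mismatch", "map file does not match its sidecar")
  }
  structure(list(intensity = m, x = meta$x, y = meta$y,
                 interpolated = meta$interpolated),
            class = "normalized_map")
}

#' Write the per-channel QC report
#'
#' TSV with columns `row,col,p_lt,p_linet,rms,flagged,rules`.
#'
#' @param features a `channel_feature_table`.
#' @param mask the matching [classify_channels()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(features, mask, path) {
  df <- data.frame(features,
                   flagged = as.integer(t(mask$flagged))[
                     (features$row - 1L) * mask$grid$n_cols + features$col],
                   rules = as.character(t(mask$rules))[
                     (features$row - 1L) * mask$grid$n_cols + features$col])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read expert labels (CSV `rater,row,col,label`)
#'
#' @param labels binary matrix raters x channels.
#' @param grid the [electrode_grid()] the channels belong to.
#' @param path CSV file.
#' @return `path` invisibly, or the raters x channels matrix.
#' @export
write_labels <- function(labels, grid, path) {
  pos <- grid_positions(grid)
  df <- do.call(rbind, lapply(seq_len(nrow(labels)), function(r)
    data.frame(rater = r, row = pos$row, col = pos$col,
               label = as.integer(labels[r, ]))))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path, grid) {
  df <- utils::read.csv(path)
  raters <- sort(unique(df$rater))
  out <- matrix(0L, length(raters), n_channels(grid))
  for (i in seq_along(raters)) {
    sub <- df[df$rater == raters[i], ]
    out[i, grid_channel_index(grid, sub$row, sub$col)] <- sub$label
  }
  out
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters; defaults are the package's standard
#' constants (k1 = 11.2, k2 = 0.2, k_line = 2.5, cap 0.85; six 500 ms
#' epochs; 12--350 Hz order-4 zero-phase filter; opening disc radius 1).
#' Serialises losslessly to JSON via [write_config()] / [read_config()].
#'
#' @param epoching an [epoching_spec()].
#' @param filter a [filter_spec()].
#' @param detector a [detector_config()].
#' @param segmentation a [segmentation_config()].
#' @param common_grid_factor oversampling factor of the inter-subject
#'   common grid.
#' @param mains_hz mains frequency.
#' @param seed integer seed for any stochastic stage.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(epoching = epoching_spec(), filter = filter_spec(),
                            detector = detector_config(),
                            segmentation = segmentation_config(),
                            common_grid_factor = 2, mains_hz = 50, seed = 1) {
  structure(list(epoching = epoching, filter = filter, detector = detector,
                 segmentation = segmentation,
                 common_grid_factor = common_grid_factor,
                 mains_hz = mains_hz, seed = seed),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path JSON file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_hdemg("format_error", sprintf("no such file: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    epoching = do.call(epoching_spec, raw$epoching),
    filter = do.call(filter_spec, raw$filter),
    detector = do.call(detector_config, raw$detector),
    segmentation = do.call(segmentation_config,
                           raw$segmentation[names(raw$segmentation) != "seed_point"]),
    common_grid_factor = raw$common_grid_factor,
    mains_hz = raw$mains_hz, seed = raw$seed)
}
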