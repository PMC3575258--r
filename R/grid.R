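#' Electrode grid geometry
#'
#' Describes a rectangular 2-D electrode array: `n_rows` electrodes in the
#' proximal--distal direction (y) and `n_cols` in the medial--lateral
#' direction (x), equally spaced by `pitch_mm`. The origin electrode marks the
#' anatomical reference used when normalising map coordinates;
#' `circumference_mm` and `segment_length_mm` are the limb measurements the
#' x and y coordinates are normalised against.
#'
#' @param n_rows,n_cols positive integers; `n_rows * n_cols >= 4`.
#' @param pitch_mm inter-electrode distance in mm (default 10).
#' @param origin_row,origin_col 1-based grid coordinates of the anatomical
#'   reference electrode (must lie inside the grid).
#' @param circumference_mm,segment_length_mm limb circumference and segment
#'   length in mm (may be `NA` if coordinate normalisation is not needed).
#' @return an object of class `electrode_grid`.
#' @examples
#' g <- electrode_grid(6, 17, circumference_mm = 250, segment_length_mm = 260)
#' g
#' @export
electrode_grid <- function(n_rows, n_cols, pitch_mm = 10,
                           origin_row = 1L, origin_col = 1L,
                           circumference_mm = NA_real_,
                           segment_length_mm = NA_real_) {
  if (!is.numeric(n_rows) || !is.numeric(n_cols) ||
      n_rows < 1 || n_cols < 1 || n_rows * n_cols < 4) {
    stop_hdemg("invalid_argument", "grid must have n_rows*n_cols >= 4 electrodes")
  }
  check_scalar_positive(pitch_mm, "pitch_mm")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  origin_row <- as.integer(origin_row); origin_col <- as.integer(origin_col)
  if (origin_row < 1L || origin_row > n_rows || origin_col < 1L || origin_col > n_cols) {
    stop_hdemg("invalid_argument", "origin electrode must lie inside the grid")
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch_mm = pitch_mm,
         origin_row = origin_row, origin_col = origin_col,
         circumference_mm = circumference_mm,
         segment_length_mm = segment_length_mm),
    class = "electrode_grid")
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d, pitch %g mm, origin (%d,%d)\n",
              x$n_rows, x$n_cols, x$pitch_mm, x$origin_row, x$origin_col))
  invisible(x)
}

n_channels <- function(grid) grid$n_rows * grid$n_cols

#' Channel index for a grid position
#'
#' Channels are stored row-major over (row, col): channel
#' `(row - 1) * n_cols + col`.
#'
#' @param grid an [electrode_grid()].
#' @param row,col 1-based grid coordinates.
#' @return integer channel index.
#' @export
grid_channel_index <- function(grid, row, col) {
  if (any(row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols)) {
    stop_hdemg("invalid_argument", "(row, col) outside grid")
  }
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Electrode positions in mm
#'
#' @param grid an [electrode_grid()].
#' @return data.frame with `row`, `col`, `x_mm` (medial--lateral) and
#'   `y_mm` (proximal--distal), in channel order.
#' @export
grid_positions <- function(grid) {
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  data.frame(row = row, col = col,
             x_mm = (col - 1L) * grid$pitch_mm,
             y_mm = (row - 1L) * grid$pitch_mm)
}

#' Multichannel grid recording
#'
#' Binds a channel x sample matrix of monopolar signals (millivolt-equivalent
#' units) to its grid geometry. Channel order is row-major over (row, col).
#'
#' @param samples numeric matrix, `n_channels x n_samples`.
#' @param fs_hz sampling rate in Hz.
#' @param grid an [electrode_grid()].
#' @param artifacts optional data.frame of ground-truth artifacts
#'   (`row`, `col`, `kind`, `severity`), as produced by [inject_artifact()].
#' @param meta optional named list of provenance metadata.
#' @return an object of class `grid_recording`.
#' @export
grid_recording <- function(samples, fs_hz, grid, artifacts = NULL, meta = list()) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop_hdemg("invalid_argument", "`samples` must be a numeric matrix")
  }
  check_scalar_positive(fs_hz, "fs_hz")
  if (nrow(samples) != n_channels(grid)) {
    stop_hdemg("dimension_mismatch",
               sprintf("samples has %d channels but grid declares %d",
                       nrow(samples), n_channels(grid)))
  }
  if (ncol(samples) < 0.5 * fs_hz) {
    stop_hdemg("invalid_argument", "recording must cover at least one 500 ms epoch")
  }
  structure(list(samples = samples, fs_hz = fs_hz, grid = grid,
                 artifacts = artifacts, meta = meta),
            class = "grid_recording")
}

#' @export
print.grid_recording <- function(x, ...) {
  cat(sprintf("<grid_recording> %d channels (%d x %d), %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), x$grid$n_rows, x$grid$n_cols,
              ncol(x$samples), x$fs_hz, ncol(x$samples) / x$fs_hz))
  n_art <- if (is.null(x$artifacts)) 0L else nrow(x$artifacts)
  if (n_art > 0L) cat(sprintf("  %d ground-truth artifact channel(s)\n", n_art))
  invisible(x)
}

# matrix of one channel per grid cell from a per-channel vector
channel_matrix <- function(grid, values) {
  matrix(values, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' Ground-truth artifact labels as a logical grid
#'
#' @param rec a [grid_recording()] carrying an `artifacts` table.
#' @return logical `n_rows x n_cols` matrix, `TRUE` at artifact channels.
#' @export
truth_mask <- function(rec) {
  m <- matrix(FALSE, rec$grid$n_rows, rec$grid$n_cols)
  if (!is.null(rec$artifacts) && nrow(rec$artifacts) > 0L) {
    m[cbind(rec$artifacts$row, rec$artifacts$col)] <- TRUE
  }
  m
}
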