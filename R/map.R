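#' Band-pass filter specification
#'
#' Defaults follow standard surface-EMG conditioning: 12--350 Hz, 4th-order
#' Butterworth, applied forward and backward (zero net phase).
#'
#' @param low_hz,high_hz corner frequencies, `0 < low < high < fs/2`.
#' @param order Butterworth design order per pass.
#' @param zero_phase apply forward-backward (default `TRUE`).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 12, high_hz = 350, order = 4, zero_phase = TRUE) {
  check_scalar_positive(low_hz, "low_hz")
  if (high_hz <= low_hz) stop_hdemg("invalid_argument", "`high_hz` must exceed `low_hz`")
  check_scalar_positive(order, "order")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

#' Zero-phase band-pass filtering
#'
#' Butterworth band-pass applied in the forward and backward direction, so
#' the net phase response is zero and the effective magnitude response is the
#' squared single-pass response.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param spec a [filter_spec()].
#' @return filtered numeric vector of the same length.
#' @export
bandpass_zero_phase <- function(signal, fs, spec = filter_spec()) {
  if (spec$high_hz >= fs / 2) {
    stop_hdemg("invalid_argument", "corner frequencies must lie below Nyquist")
  }
  if (length(signal) <= 3 * spec$order) {
    stop_hdemg("invalid_argument", "signal too short for the filter order")
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  if (spec$zero_phase) {
    drop(filtfilt_matrix(bf, matrix(signal, ncol = 1)))
  } else {
    as.numeric(signal::filter(bf, signal))
  }
}

# direct-form IIR filter applied down the columns of a matrix,
# zero initial conditions (column-wise equivalent of signal::filter)
iir_filter_matrix <- function(b, a, x) {
  nb <- length(b)
  strip <- function(v, n) matrix(as.numeric(v), nrow = n)
  if (nb > 1L) {
    xp <- rbind(matrix(0, nb - 1L, ncol(x)), x)
    v <- strip(stats::filter(xp, b / a[1], method = "convolution", sides = 1),
               nrow(xp))
    v <- v[nb:nrow(xp), , drop = FALSE]
  } else {
    v <- x * (b / a[1])
  }
  if (length(a) > 1L) {
    v <- strip(stats::filter(v, -a[-1] / a[1], method = "recursive"), nrow(v))
  }
  v
}

# forward-backward filtering of every column; matches signal::filtfilt
# (2*order zero-padding at the tail before the reversed pass)
filtfilt_matrix <- function(bf, x) {
  b <- bf$b; a <- bf$a
  n <- nrow(x)
  pad <- 2L * max(length(a), length(b))
  y <- iir_filter_matrix(b, a, rbind(x, matrix(0, pad, ncol(x))))
  y <- iir_filter_matrix(b, a, y[nrow(y):1L, , drop = FALSE])
  y[nrow(y):1L, , drop = FALSE][seq_len(n), , drop = FALSE]
}

#' Locate the steadiest force window
#'
#' Slides a window of `duration_s` over the force trace (100 ms stride) and
#' returns the start of the window with minimal variance; ties break to the
#' earliest window.
#'
#' @param force numeric force/torque trace.
#' @param fs sampling rate (Hz).
#' @param duration_s window length in seconds (default 3).
#' @param stride_s stride of the search (default 0.1).
#' @return 1-based start sample of the selected window.
#' @export
select_steady_segment <- function(force, fs, duration_s = 3, stride_s = 0.1) {
  len <- round(duration_s * fs)
  if (length(force) < len) {
    stop_hdemg("length_error", "force record shorter than the requested window")
  }
  stride <- max(1L, round(stride_s * fs))
  starts <- seq(1L, length(force) - len + 1L, by = stride)
  cs <- cumsum(c(0, force)); cs2 <- cumsum(c(0, force^2))
  v <- vapply(starts, function(s) {
    sm <- cs[s + len] - cs[s]; sq <- cs2[s + len] - cs2[s]
    sq / len - (sm / len)^2
  }, numeric(1))
  starts[which.min(v)]
}

#' Compute the RMS activation map
#'
#' Per channel: zero-phase band-pass filter the analysis window, split it
#' into `M` non-overlapping epochs (default six 500 ms epochs = 3 s), take
#' the RMS of each epoch and average the `M` values. The result is the 2-D
#' activation image whose pixel (i, j) is the mean epoch RMS of the channel
#' at that electrode.
#'
#' @param rec a [grid_recording()].
#' @param window_start first sample of the analysis window (e.g. from
#'   [select_steady_segment()]).
#' @param epoching an [epoching_spec()].
#' @param filt a [filter_spec()]; `NULL` skips filtering.
#' @return an object of class `activation_map`: `intensity` matrix
#'   (n_rows x n_cols), physical coordinates `x_mm` / `y_mm`, and provenance.
#' @export
compute_map <- function(rec, window_start = 1L, epoching = epoching_spec(),
                        filt = filter_spec()) {
  fs <- rec$fs_hz
  len <- epoch_length_samples(epoching, fs)
  need <- window_start + epoching$n_epochs * len - 1L
  if (window_start < 1L || need > ncol(rec$samples)) {
    stop_hdemg("length_error", "analysis window not covered by the recording")
  }
  idx <- window_start - 1L + seq_len(epoching$n_epochs * len)
  grid <- rec$grid
  xmat <- t(rec$samples[, idx, drop = FALSE])     # samples x channels
  if (!is.null(filt)) {
    if (filt$high_hz >= fs / 2) {
      stop_hdemg("invalid_argument", "corner frequencies must lie below Nyquist")
    }
    bf <- signal::butter(filt$order, c(filt$low_hz, filt$high_hz) / (fs / 2),
                         type = "pass")
    if (filt$zero_phase) {
      xmat <- filtfilt_matrix(bf, xmat)
    } else {
      xmat <- iir_filter_matrix(bf$b, bf$a, xmat)
    }
  }
  # per-epoch RMS, averaged over epochs, channel by channel
  em <- matrix(xmat, nrow = len)                  # len x (n_epochs * nch)
  er <- sqrt(colMeans(em^2))
  intens <- colMeans(matrix(er, nrow = epoching$n_epochs))
  structure(list(intensity = channel_matrix(grid, intens),
                 x_mm = (seq_len(grid$n_cols) - 1) * grid$pitch_mm,
                 y_mm = (seq_len(grid$n_rows) - 1) * grid$pitch_mm,
                 grid = grid, interpolated = NULL,
                 provenance = list(window_start = window_start,
                                   epoching = epoching, filter = filt)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> %d x %d, intensity [%.4g, %.4g]%s\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$intensity), max(x$intensity),
              if (length(x$interpolated)) sprintf(", %d channel(s) interpolated",
                                                  nrow(x$interpolated)) else ""))
  invisible(x)
}

#' Replace flagged channels by surface interpolation
#'
#' Intensity values of flagged channels are replaced by triangle-based
#' bicubic interpolation (Akima splines on a Delaunay triangulation of the
#' non-flagged electrode positions). Flagged cells falling outside the convex
#' hull of the non-flagged positions, where the triangulation does not
#' extend, are filled with the value of the nearest non-flagged channel
#' (ties averaged). Non-flagged cells are returned bit-unchanged.
#'
#' @param map an [compute_map()] result.
#' @param mask an [classify_channels()] result or logical matrix of flagged
#'   channels.
#' @return the map with flagged cells replaced and the replacement list
#'   recorded in `$interpolated`.
#' @export
replace_artifact_values <- function(map, mask) {
  flagged <- if (inherits(mask, "artifact_mask")) mask$flagged else mask
  if (!all(dim(flagged) == dim(map$intensity))) {
    stop_hdemg("invalid_argument", "mask shape does not match the map")
  }
  nbad <- sum(flagged)
  if (nbad == 0L) return(map)
  ntot <- length(flagged)
  if (nbad / ntot >= 0.5 || ntot - nbad < 3L) {
    stop_hdemg("interpolation_infeasible",
               sprintf("%d of %d channels flagged; interpolation not possible",
                       nbad, ntot))
  }
  I <- map$intensity
  pos_col <- matrix(rep(map$x_mm, each = nrow(I)), nrow(I))
  pos_row <- matrix(rep(map$y_mm, times = ncol(I)), nrow(I))
  good <- !flagged
  gx <- pos_col[good]; gy <- pos_row[good]; gz <- I[good]
  bx <- pos_col[flagged]; by <- pos_row[flagged]
  vals <- tryCatch(
    interp::interpp(gx, gy, gz, xo = bx, yo = by, linear = FALSE,
                    extrap = FALSE)$z,
    error = function(e) stop_hdemg("interpolation_infeasible", conditionMessage(e)))
  # hull-exterior fallback: nearest non-flagged channel (ties averaged)
  outside <- which(is.na(vals))
  for (i in outside) {
    d2 <- (gx - bx[i])^2 + (gy - by[i])^2
    vals[i] <- mean(gz[d2 <= min(d2) + 1e-9])
  }
  I[flagged] <- vals
  map$intensity <- I
  repl <- which(flagged, arr.ind = TRUE)
  map$interpolated <- data.frame(row = repl[, 1], col = repl[, 2], value = vals)
  map
}
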