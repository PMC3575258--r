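#' Epoching specification
#'
#' Non-overlapping analysis epochs: by default six 500 ms epochs, i.e. the
#' 3 s analysis window used for both detection features and activation maps.
#'
#' @param epoch_ms epoch length in milliseconds (default 500).
#' @param n_epochs number of contiguous epochs (default 6).
#' @param window taper applied before the FFT; `"none"` (rectangular) is the
#'   default and currently the only option.
#' @return an object of class `epoching_spec`.
#' @export
epoching_spec <- function(epoch_ms = 500, n_epochs = 6, window = "none") {
  check_scalar_positive(epoch_ms, "epoch_ms")
  if (!is.numeric(n_epochs) || n_epochs < 1) {
    stop_hdemg("invalid_argument", "`n_epochs` must be a positive integer")
  }
  window <- match.arg(window, "none")
  structure(list(epoch_ms = epoch_ms, n_epochs = as.integer(n_epochs),
                 window = window),
            class = "epoching_spec")
}

epoch_length_samples <- function(spec, fs) round(spec$epoch_ms * fs / 1000)

#' Split a signal into non-overlapping epochs
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param spec an [epoching_spec()].
#' @param start_sample 1-based index of the first sample of the first epoch.
#' @return list of `n_epochs` numeric vectors of `round(epoch_ms * fs / 1000)`
#'   samples each.
#' @export
epoch_segments <- function(signal, fs, spec = epoching_spec(), start_sample = 1L) {
  len <- epoch_length_samples(spec, fs)
  need <- start_sample + spec$n_epochs * len - 1L
  if (need > length(signal) || start_sample < 1L) {
    stop_hdemg("length_error",
               sprintf("need %d samples from sample %d but signal has %d",
                       spec$n_epochs * len, start_sample, length(signal)))
  }
  lapply(seq_len(spec$n_epochs) - 1L, function(m) {
    signal[(start_sample + m * len):(start_sample + (m + 1L) * len - 1L)]
  })
}

#' Fraction of signal power inside frequency bands
#'
#' Estimates the power spectral density of one epoch by the magnitude-squared
#' FFT (rectangular window) and returns the power in the given bands divided
#' by the total power over (0, fs/2] (DC excluded).
#'
#' @param epoch numeric vector (one epoch).
#' @param fs sampling rate (Hz).
#' @param bands list of `c(lo_hz, hi_hz)` pairs, `0 <= lo < hi <= fs/2`; a bin
#'   of centre frequency f contributes when `lo <= f <= hi` for some band.
#' @return fraction in `[0, 1]` (0 for an all-zero epoch).
#' @export
band_power_fraction <- function(epoch, fs, bands) {
  if (length(epoch) == 0L) stop_hdemg("invalid_argument", "empty epoch")
  for (b in bands) {
    if (b[1] < 0 || b[2] <= b[1] || b[2] > fs / 2) {
      stop_hdemg("invalid_argument", "bands must satisfy 0 <= lo < hi <= fs/2")
    }
  }
  n <- length(epoch)
  p <- Mod(stats::fft(epoch))^2
  k <- seq_len(floor(n / 2))                 # positive-frequency bins, DC excluded
  f <- k * fs / n
  pk <- p[k + 1L]
  tot <- sum(pk)
  if (tot == 0) return(0)
  sel <- rep(FALSE, length(k))
  for (b in bands) sel <- sel | (f >= b[1] & f <= b[2])
  sum(pk[sel]) / tot
}

line_bands <- function(mains_hz = 50, n_lines = 5, half_bw_hz = 2) {
  lapply(seq_len(n_lines), function(h) c(mains_hz * h - half_bw_hz,
                                         mains_hz * h + half_bw_hz))
}

#' Per-channel detection features
#'
#' Computes, for every channel of a grid recording, the three artifact
#' detection features, each averaged over the epochs of `spec`
#' (default six 500 ms epochs = 3 s):
#' \describe{
#'   \item{`p_lt`}{relative power of low-frequency components, 0--12 Hz;}
#'   \item{`p_linet`}{relative power at the mains frequency and its first four
#'     harmonics (50, 100, 150, 200, 250 Hz by default), each line taken with
#'     a configurable half-bandwidth;}
#'   \item{`rms`}{root-mean-square amplitude (signal units).}
#' }
#' An all-zero channel gets both fractions 0 (not `NaN`) so that the
#' neighbourhood RMS rule, not the spectral rules, is what flags dead
#' channels.
#'
#' @param rec a [grid_recording()].
#' @param spec an [epoching_spec()].
#' @param start_sample first sample of the analysis window.
#' @param low_band `c(lo, hi)` Hz for `p_lt` (default `c(0, 12)`).
#' @param mains_hz mains frequency (default 50; set 60 for 60 Hz mains).
#' @param n_lines number of spectral lines including the fundamental.
#' @param half_bw_hz half-bandwidth around each line, Hz.
#' @return a `channel_feature_table`: data.frame with columns `row`, `col`,
#'   `p_lt`, `p_linet`, `rms` in channel order, with the grid attached as an
#'   attribute.
#' @export
channel_features <- function(rec, spec = epoching_spec(), start_sample = 1L,
                             low_band = c(0, 12), mains_hz = 50, n_lines = 5,
                             half_bw_hz = 2) {
  fs <- rec$fs_hz
  len <- epoch_length_samples(spec, fs)
  need <- start_sample + spec$n_epochs * len - 1L
  if (need > ncol(rec$samples) || start_sample < 1L) {
    stop_hdemg("length_error", "recording does not cover the analysis window")
  }
  nch <- nrow(rec$samples)
  # epochs of all channels as columns of one matrix -> single mvfft call
  idx <- start_sample - 1L + seq_len(spec$n_epochs * len)
  seg <- rec$samples[, idx, drop = FALSE]
  em <- matrix(t(seg), nrow = len)             # len x (n_epochs * nch)
  p <- Mod(stats::mvfft(em))^2
  k <- seq_len(floor(len / 2))
  f <- k * fs / len
  pk <- p[k + 1L, , drop = FALSE]
  tot <- colSums(pk)
  sel_low <- f >= low_band[1] & f <= low_band[2]
  sel_line <- rep(FALSE, length(k))
  for (b in line_bands(mains_hz, n_lines, half_bw_hz)) {
    sel_line <- sel_line | (f >= b[1] & f <= b[2])
  }
  frac <- function(sel) {
    out <- colSums(pk[sel, , drop = FALSE])
    ifelse(tot > 0, out / tot, 0)
  }
  p_lt_e <- frac(sel_low)
  p_line_e <- frac(sel_line)
  rms_e <- sqrt(colMeans(em^2))
  by_ch <- function(v) colMeans(matrix(v, nrow = spec$n_epochs))
  pos <- grid_positions(rec$grid)
  out <- data.frame(row = pos$row, col = pos$col,
                    p_lt = by_ch(p_lt_e), p_linet = by_ch(p_line_e),
                    rms = by_ch(rms_e))
  attr(out, "grid") <- rec$grid
  attr(out, "epoching") <- spec
  class(out) <- c("channel_feature_table", "data.frame")
  out
}

feature_grid <- function(features) {
  g <- attr(features, "grid")
  if (is.null(g)) stop_hdemg("invalid_argument", "feature table lacks a grid attribute")
  g
}

# per-feature matrix in grid layout
feature_matrix <- function(features, which) {
  channel_matrix(feature_grid(features), features[[which]])
}
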