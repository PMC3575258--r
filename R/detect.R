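#' Detector configuration
#'
#' Constants of the threshold expert system for low-quality-channel
#' detection. `k1` scales the low-frequency threshold, `k_line` the
#' power-line threshold (always capped at `line_cap`), and `k2` the
#' neighbourhood RMS threshold; `iqr_mult` is the interquartile-range
#' multiplier used both for reference-set selection and for the additive IQR
#' term of the global thresholds.
#'
#' The neighbourhood RMS rule direction is configurable: with `"below"`
#' (default) a channel is flagged when its RMS falls under the neighbourhood
#' threshold, with `"above"` when it exceeds the threshold reflected about
#' the neighbourhood level, `"both"` combines the two. `rms_deficit_frac`
#' requires the channel RMS to sit below that fraction of the neighbourhood
#' threshold before the rule fires (1 recovers the bare threshold
#' comparison); see the package vignette for why a genuine deficit is
#' required.
#'
#' @param k1 low-frequency threshold constant (default 11.2).
#' @param k2 neighbourhood RMS margin constant (default 0.2).
#' @param k_line power-line threshold constant (default 2.5).
#' @param line_cap hard cap on the power-line threshold (default 0.85).
#' @param iqr_mult IQR multiplier (default 1.5).
#' @param rms_rule_direction `"below"`, `"above"` or `"both"`.
#' @param rms_deficit_frac fraction of the neighbourhood threshold the
#'   channel RMS must fall short of (default 0.5).
#' @param k_scales_whole_expression if `TRUE`, `k1`/`k_line` multiply the
#'   whole `median + iqr_mult * IQR` expression instead of the median only.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(k1 = 11.2, k2 = 0.2, k_line = 2.5, line_cap = 0.85,
                            iqr_mult = 1.5,
                            rms_rule_direction = c("below", "above", "both"),
                            rms_deficit_frac = 0.5,
                            k_scales_whole_expression = FALSE) {
  check_scalar_positive(k1, "k1")
  check_scalar_positive(k2, "k2")
  check_scalar_positive(k_line, "k_line")
  if (!is.numeric(line_cap) || line_cap <= 0 || line_cap > 1) {
    stop_hdemg("invalid_argument", "`line_cap` must be in (0, 1]")
  }
  check_scalar_positive(rms_deficit_frac, "rms_deficit_frac")
  structure(list(k1 = k1, k2 = k2, k_line = k_line, line_cap = line_cap,
                 iqr_mult = iqr_mult,
                 rms_rule_direction = match.arg(rms_rule_direction),
                 rms_deficit_frac = rms_deficit_frac,
                 k_scales_whole_expression = isTRUE(k_scales_whole_expression)),
            class = "detector_config")
}

#' Select the reference channel set
#'
#' Reference channels are those whose `p_lt` and `p_linet` both lie within
#' `iqr_mult` interquartile ranges of the respective set medians. When a
#' feature's IQR is zero the comparison degrades to equality with the median.
#'
#' @param features a `channel_feature_table` (see [channel_features()]).
#' @param iqr_mult IQR multiplier (default 1.5).
#' @return an object of class `reference_set`: member channel indices plus
#'   the medians and IQRs of the member features.
#' @export
select_reference <- function(features, iqr_mult = 1.5) {
  if (nrow(features) < 4L) stop_hdemg("invalid_argument", "need at least 4 channels")
  within <- function(x) {
    med <- stats::median(x); iqr <- stats::IQR(x)
    if (iqr == 0) abs(x - med) <= 1e-12 * max(1, abs(med))
    else abs(x - med) < iqr_mult * iqr
  }
  keep <- within(features$p_lt) & within(features$p_linet)
  if (!any(keep)) stop_hdemg("no_reference_error", "reference set is empty")
  members <- which(keep)
  structure(list(members = members,
                 median_p_lt = stats::median(features$p_lt[members]),
                 iqr_p_lt = stats::IQR(features$p_lt[members]),
                 median_p_linet = stats::median(features$p_linet[members]),
                 iqr_p_linet = stats::IQR(features$p_linet[members]),
                 n_total = nrow(features)),
            class = "reference_set")
}

#' Global spectral thresholds from the reference set
#'
#' `thresh_lt = k1 * median(p_lt, ref) + iqr_mult * IQR(p_lt, ref)` and
#' `thresh_linet = min(line_cap, k_line * median(p_linet, ref) +
#' iqr_mult * IQR(p_linet, ref))`.
#'
#' @param ref a [select_reference()] result.
#' @param cfg a [detector_config()].
#' @return list with `thresh_lt` and `thresh_linet`.
#' @export
compute_global_thresholds <- function(ref, cfg = detector_config()) {
  comb <- function(k, med, iqr) {
    if (cfg$k_scales_whole_expression) k * (med + cfg$iqr_mult * iqr)
    else k * med + cfg$iqr_mult * iqr
  }
  list(thresh_lt = comb(cfg$k1, ref$median_p_lt, ref$iqr_p_lt),
       thresh_linet = min(cfg$line_cap,
                          comb(cfg$k_line, ref$median_p_linet, ref$iqr_p_linet)))
}

# reflect an index into 1..n (mirror about the border cell)
reflect_index <- function(i, n) {
  out <- ifelse(i < 1L, 2L - i, ifelse(i > n, 2L * n - i, i))
  if (any(out < 1L | out > n)) {
    stop_hdemg("undefined_neighborhood_error",
               "grid too small to form the neighbour pairs")
  }
  out
}

#' Neighbourhood RMS threshold (one channel)
#'
#' Forms three neighbour pairs around channel (row, col) from the RMS grid:
#' the longitudinal pair (rows above/below, same column) and the two
#' diagonal pairs; missing neighbours at the array border are mirror-padded.
#' Returns `min(pair means) + k2 * max(pair standard deviations)`, where the
#' standard deviation of a 2-element pair uses the n-1 denominator
#' (`|a - b| / sqrt(2)`).
#'
#' @param features a `channel_feature_table`.
#' @param row,col channel position.
#' @param k2 margin constant.
#' @return the threshold (signal units).
#' @export
neighbor_rms_threshold <- function(features, row, col, k2 = 0.2) {
  grid <- feature_grid(features)
  if (grid$n_rows < 2L || grid$n_cols < 2L) {
    stop_hdemg("undefined_neighborhood_error",
               "neighbour pairs need at least 2 rows and 2 columns")
  }
  rmat <- feature_matrix(features, "rms")
  thr <- neighbor_rms_threshold_grid(rmat, k2)
  thr[row, col]
}

# vectorised Eq.-style neighbourhood threshold over the whole grid
neighbor_rms_threshold_grid <- function(rmat, k2) {
  nr <- nrow(rmat); nc <- ncol(rmat)
  ri <- seq_len(nr); ci <- seq_len(nc)
  up <- reflect_index(ri - 1L, nr); dn <- reflect_index(ri + 1L, nr)
  lf <- reflect_index(ci - 1L, nc); rt <- reflect_index(ci + 1L, nc)
  pair_stats <- function(a, b) {
    list(mean = (a + b) / 2, sd = abs(a - b) / sqrt(2))
  }
  pa <- pair_stats(rmat[up, , drop = FALSE], rmat[dn, , drop = FALSE])
  pb <- pair_stats(rmat[up, lf, drop = FALSE], rmat[dn, rt, drop = FALSE])
  pc <- pair_stats(rmat[dn, lf, drop = FALSE], rmat[up, rt, drop = FALSE])
  pmin(pa$mean, pb$mean, pc$mean) + k2 * pmax(pa$sd, pb$sd, pc$sd)
}

#' Classify channels as artifact / non-artifact
#'
#' One-shot decision over the three rules: a channel is flagged when its
#' low-frequency fraction exceeds `thresh_lt` ("lowfreq"), its line fraction
#' exceeds `thresh_linet` ("line"), or its RMS violates the neighbourhood
#' rule ("rms"). Thresholds are computed once from the reference subset
#' before any classification (no iterative re-referencing).
#'
#' @param features a `channel_feature_table`.
#' @param cfg a [detector_config()].
#' @return an object of class `artifact_mask`: logical `flagged` grid, the
#'   per-channel triggering `rules`, and the thresholds used.
#' @export
classify_channels <- function(features, cfg = detector_config()) {
  grid <- feature_grid(features)
  ref <- select_reference(features, cfg$iqr_mult)
  glob <- compute_global_thresholds(ref, cfg)
  p_lt <- feature_matrix(features, "p_lt")
  p_linet <- feature_matrix(features, "p_linet")
  rmat <- feature_matrix(features, "rms")
  rule_low <- p_lt > glob$thresh_lt
  rule_line <- p_linet > glob$thresh_linet
  if (grid$n_rows >= 2L && grid$n_cols >= 2L) {
    thr_rms <- neighbor_rms_threshold_grid(rmat, cfg$k2)
    below <- rmat < cfg$rms_deficit_frac * thr_rms
    # "above": same margin reflected about the neighbourhood level
    above <- rmat > thr_rms / cfg$rms_deficit_frac
    rule_rms <- switch(cfg$rms_rule_direction,
                       below = below, above = above, both = below | above)
  } else {
    thr_rms <- matrix(NA_real_, grid$n_rows, grid$n_cols)
    rule_rms <- matrix(FALSE, grid$n_rows, grid$n_cols)
  }
  flagged <- rule_low | rule_line | rule_rms
  rules <- matrix("", grid$n_rows, grid$n_cols)
  rules[] <- paste0(ifelse(rule_low, "lowfreq;", ""),
                    ifelse(rule_line, "line;", ""),
                    ifelse(rule_rms, "rms;", ""))
  rules[] <- sub(";$", "", rules)
  structure(list(flagged = flagged, rules = rules,
                 thresholds = list(thresh_lt = glob$thresh_lt,
                                   thresh_linet = glob$thresh_linet,
                                   thresh_rms = thr_rms),
                 reference = ref, config = cfg, grid = grid),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d/%d channels flagged\n",
              sum(x$flagged), length(x$flagged)))
  invisible(x)
}

#' Detection performance against ground truth
#'
#' @param mask an [classify_channels()] result or a logical matrix.
#' @param truth logical matrix (or vector) of the same shape, `TRUE` at
#'   artifact channels.
#' @return an object of class `detection_performance` with confusion counts
#'   `tp`, `fp`, `tn`, `fn` and indexes `s` (sensitivity), `sp`
#'   (specificity), `p` (precision) and `acc`; an index with a zero
#'   denominator is `NA` (undefined).
#' @export
evaluate_detection <- function(mask, truth) {
  pred <- if (inherits(mask, "artifact_mask")) mask$flagged else mask
  if (length(pred) != length(truth)) {
    stop_hdemg("invalid_argument", "mask and truth shapes differ")
  }
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 s = safe(tp, tp + fn), sp = safe(tn, tn + fp),
                 p = safe(tp, tp + fp), acc = safe(tp + tn, tp + fp + tn + fn)),
            class = "detection_performance")
}

#' @export
print.detection_performance <- function(x, ...) {
  cat(sprintf("<detection_performance> TP=%d FP=%d TN=%d FN=%d | S=%.4f SP=%.4f P=%.4f Acc=%.4f\n",
              x$tp, x$fp, x$tn, x$fn, x$s, x$sp, x$p, x$acc))
  invisible(x)
}

# pooled confusion over labelled sets for one constant pair
pooled_performance <- function(labeled_sets, cfg) {
  tp <- fp <- tn <- fn <- 0L
  for (ls in labeled_sets) {
    mask <- classify_channels(ls$features, cfg)
    perf <- evaluate_detection(mask, ls$truth)
    tp <- tp + perf$tp; fp <- fp + perf$fp; tn <- tn + perf$tn; fn <- fn + perf$fn
  }
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       s = safe(tp, tp + fn), sp = safe(tn, tn + fp),
       p = safe(tp, tp + fp), acc = safe(tp + tn, tp + fp + tn + fn))
}

#' Tune detector constants on labelled sets
#'
#' Grid search over `(k1, k2)`; for each pair, confusion counts are pooled
#' over all labelled sets and the operating point is chosen as the minimum
#' Euclidean distance to the ideal corner: `(0, 1)` in (1-SP, S) space for
#' the ROC criterion, `(1, 1)` in (SP, P) space for the precision--recall
#' criterion. Ties break towards higher accuracy, then smaller `k1`, then
#' smaller `k2`.
#'
#' @param labeled_sets list of `list(features = <channel_feature_table>,
#'   truth = <logical matrix>)`.
#' @param k1_grid,k2_grid candidate constants.
#' @param criterion `"roc"` or `"pr"`.
#' @param cfg_base a [detector_config()] supplying the remaining constants.
#' @return list with the selected `k1`, `k2`, the selected pooled
#'   `performance`, and the full `curve` data.frame
#'   (`k1, k2, s, sp, p, acc, distance`).
#' @export
tune_constants <- function(labeled_sets, k1_grid = c(2, 4, 7.1, 11.2, 16),
                           k2_grid = c(0.05, 0.1, 0.2, 0.5), criterion = c("roc", "pr"),
                           cfg_base = detector_config()) {
  criterion <- match.arg(criterion)
  if (length(k1_grid) == 0L || length(k2_grid) == 0L) {
    stop_hdemg("invalid_argument", "constant grids must be non-empty")
  }
  if (!any(vapply(labeled_sets, function(ls) any(ls$truth), logical(1)))) {
    stop_hdemg("invalid_argument", "need at least one positive label")
  }
  rows <- list()
  for (k1 in k1_grid) for (k2 in k2_grid) {
    cfg <- cfg_base
    cfg$k1 <- k1; cfg$k2 <- k2
    perf <- pooled_performance(labeled_sets, cfg)
    d <- if (criterion == "roc") {
      sqrt((1 - perf$sp - 0)^2 + (perf$s - 1)^2)
    } else {
      sqrt((perf$sp - 1)^2 + (perf$p - 1)^2)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(k1 = k1, k2 = k2, s = perf$s, sp = perf$sp, p = perf$p,
                 acc = perf$acc, distance = d)
  }
  curve <- do.call(rbind, rows)
  ok <- is.finite(curve$distance)
  if (!any(ok)) stop_hdemg("tuning_failed", "all operating points undefined")
  cand <- curve[ok, ]
  ord <- order(cand$distance, -cand$acc, cand$k1, cand$k2)
  best <- cand[ord[1L], ]
  cfg <- cfg_base; cfg$k1 <- best$k1; cfg$k2 <- best$k2
  list(k1 = best$k1, k2 = best$k2, criterion = criterion,
       performance = pooled_performance(labeled_sets, cfg), curve = curve)
}

#' Majority vote over expert labels
#'
#' @param labels binary matrix, raters x channels (an odd number >= 3 of
#'   raters).
#' @return integer vector of per-channel modes (0/1).
#' @export
majority_vote <- function(labels) {
  labels <- as.matrix(labels)
  n <- nrow(labels)
  if (n < 3L || n %% 2L == 0L) {
    stop_hdemg("invalid_argument", "need an odd number of raters >= 3")
  }
  as.integer(colSums(labels) > n / 2)
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Chance-corrected agreement between raters assigning each item to one of
#' two categories (artifact / non-artifact). Returns 1 for perfect agreement
#' and approximately 0 for independent random raters; when every rater uses
#' a single category on every item the index is undefined (no chance
#' variance) and `NA` is returned.
#'
#' @param labels binary matrix, raters x items (>= 2 raters, >= 2 items).
#' @return kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
fleiss_kappa <- function(labels) {
  labels <- as.matrix(labels)
  n <- nrow(labels); N <- ncol(labels)
  if (n < 2L || N < 2L) stop_hdemg("invalid_argument", "need >= 2 raters and >= 2 items")
  n1 <- colSums(labels)                        # raters voting category 1 per item
  nij <- cbind(n - n1, n1)
  p_i <- (rowSums(nij^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  pj <- colSums(nij) / (N * n)
  pe <- sum(pj^2)
  if (abs(1 - pe) < .Machine$double.eps^0.5) return(NA_real_)
  (p_bar - pe) / (1 - pe)
}
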