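# Shared fixtures, built in code at test time.

fixture_grid <- function(n_rows = 6, n_cols = 17) {
  electrode_grid(n_rows, n_cols, pitch_mm = 10,
                 origin_row = max(1, n_rows %/% 2), origin_col = max(1, n_cols %/% 2),
                 circumference_mm = 260, segment_length_mm = 250)
}

fixture_blobs <- function(grid = fixture_grid()) {
  w <- (grid$n_cols - 1) * grid$pitch_mm
  h <- (grid$n_rows - 1) * grid$pitch_mm
  list(activation_blob(0.3 * w, h / 2, peak = 1.0, sd_mm = c(28, 40)),
       activation_blob(0.8 * w, h / 2, peak = 0.6, sd_mm = c(25, 40)))
}

fixture_recording <- function(seed = 1, grid = fixture_grid(),
                              blobs = fixture_blobs(grid)) {
  generate_recording(grid, blobs, duration_s = 3, fs_hz = 2048, seed = seed)
}

# a small, fast effect model for pipeline-level tests
small_effect_model <- function(...) {
  g <- function() electrode_grid(6, 10, origin_row = 3, origin_col = 5,
                                 circumference_mm = 260, segment_length_mm = 250)
  task_effect_model(
    muscles = list(
      agonist    = list(grid = g(), centre_mm = c(40, 25), sd_mm = c(35, 45)),
      antagonist = list(grid = g(), centre_mm = c(50, 25), sd_mm = c(35, 45))),
    coactivation = rbind(agonist    = c(flexion = 1.0, extension = 0.3),
                         antagonist = c(flexion = 0.3, extension = 1.0)),
    ...)
}

# labelled sets for detector training/validation: grid recordings with
# injected ground-truth artifacts at a 0-13% prevalence
make_labeled_sets <- function(n_sets, seed = 1, grid = fixture_grid(),
                              prevalence = c(0, 0.13)) {
  sets <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    sseed <- seed + 1000L * s
    rec <- fixture_recording(seed = sseed, grid = grid)
    set.seed(sseed + 1L)
    rate <- stats::runif(1, prevalence[1], prevalence[2])
    n_art <- round(rate * nrow(rec$samples))
    if (n_art > 0) {
      idx <- sample.int(nrow(rec$samples), n_art)
      kinds <- sample(c("drift", "powerline", "isolated_amplitude"), n_art,
                      replace = TRUE)
      sevs <- ifelse(kinds == "isolated_amplitude",
                     stats::runif(n_art, 0.02, 0.1), stats::runif(n_art, 3, 8))
      for (i in seq_len(n_art)) {
        r <- (idx[i] - 1L) %/% grid$n_cols + 1L
        c <- (idx[i] - 1L) %% grid$n_cols + 1L
        rec <- inject_artifact(rec, r, c, kinds[i], sevs[i], seed = sseed + 10L + i)
      }
    }
    sets[[s]] <- list(features = channel_features(rec), truth = truth_mask(rec))
  }
  sets
}

# hand-built feature table on a given grid (for precise detector-rule tests)
feature_table <- function(grid, p_lt, p_linet, rms) {
  pos <- grid_positions(grid)
  expand_val <- function(v) if (length(v) == 1L) rep(v, nrow(pos)) else as.vector(t(v))
  out <- data.frame(row = pos$row, col = pos$col,
                    p_lt = expand_val(p_lt), p_linet = expand_val(p_linet),
                    rms = expand_val(rms))
  attr(out, "grid") <- grid
  class(out) <- c("channel_feature_table", "data.frame")
  out
}
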