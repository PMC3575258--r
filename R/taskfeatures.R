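#' Full per-condition processing of one grid recording
#'
#' Runs the single-recording stages in order: detection features, artifact
#' classification, activation map, replacement of flagged channels, h-dome
#' segmentation (seeded at the anatomical reference electrode), projections
#' and intensity features.
#'
#' @param rec a [grid_recording()].
#' @param detector a [detector_config()].
#' @param segmentation a [segmentation_config()]; its `seed_point` defaults
#'   to the grid's origin electrode.
#' @param epoching an [epoching_spec()].
#' @param filt a [filter_spec()].
#' @param window_start first sample of the analysis window.
#' @return list with `features`, `mask`, `map` (after replacement), `seg`,
#'   and the scalar features `rms_av_hd`, `rms_av_bip`, `mu_x`, `mu_y`
#'   (`mu` in limb-normalised units when the grid carries limb metadata,
#'   else mm).
#' @export
process_recording <- function(rec, detector = detector_config(),
                              segmentation = segmentation_config(),
                              epoching = epoching_spec(), filt = filter_spec(),
                              window_start = 1L) {
  grid <- rec$grid
  feats <- channel_features(rec, epoching, window_start)
  mask <- classify_channels(feats, detector)
  map <- compute_map(rec, window_start, epoching, filt)
  map <- tryCatch(replace_artifact_values(map, mask),
                  hdemg_error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    map
                  })
  if (is.null(segmentation$seed_point)) {
    segmentation$seed_point <- c(grid$origin_row, grid$origin_col)
  }
  # a narrow dome can be erased entirely by the opening; escalate the dome
  # height (wider support slab) until a region survives
  seg <- NULL
  h_try <- if (segmentation$h_mode == "fraction") {
    unique(c(segmentation$h, 0.5, 0.75))
  } else {
    segmentation$h
  }
  for (h in h_try) {
    segmentation$h <- h
    seg <- tryCatch(extract_active_regions(map, segmentation),
                    no_region_error = function(e) NULL)
    if (!is.null(seg)) break
  }
  if (is.null(seg)) {
    stop_hdemg("no_region_error", "no active region at any dome height")
  }
  px <- project_map(seg, "x"); py <- project_map(seg, "y")
  mu_x <- projection_median(px); mu_y <- projection_median(py)
  if (!is.na(grid$circumference_mm) && grid$circumference_mm > 0) {
    mu_x <- (mu_x - (grid$origin_col - 1) * grid$pitch_mm) / grid$circumference_mm
  }
  if (!is.na(grid$segment_length_mm) && grid$segment_length_mm > 0) {
    mu_y <- (mu_y - (grid$origin_row - 1) * grid$pitch_mm) / grid$segment_length_mm
  }
  bip_b <- if (grid$origin_row < grid$n_rows) {
    c(grid$origin_row + 1L, grid$origin_col)
  } else {
    c(grid$origin_row - 1L, grid$origin_col)
  }
  rms_bip <- bipolar_rms(rec, c(grid$origin_row, grid$origin_col), bip_b,
                         window_start, epoching, filt)
  list(features = feats, mask = mask, map = map, seg = seg,
       rms_av_hd = region_mean_intensity(map, seg),
       rms_av_bip = rms_bip, mu_x = mu_x, mu_y = mu_y)
}

#' Simulate a task dataset and extract the per-condition feature table
#'
#' Streaming counterpart of [simulate_task_dataset()]: conditions are
#' generated, processed with [process_recording()] and discarded one at a
#' time, so full-size datasets (12 subjects x 4 tasks x 3 efforts x 5
#' muscle arrays) fit comfortably in memory.
#'
#' @inheritParams simulate_task_dataset
#' @param detector,segmentation,epoching,filt processing configuration
#'   passed to [process_recording()].
#' @return data.frame with one row per (subject, task, effort, muscle):
#'   `rms_av_hd`, `rms_av_bip`, `mu_x`, `mu_y`.
#' @export
simulate_task_features <- function(n_subjects = 12,
                                   tasks = c("flexion", "extension", "pronation", "supination"),
                                   efforts = c(10, 30, 50),
                                   effect_model = task_effect_model(),
                                   seed = 1,
                                   detector = detector_config(),
                                   segmentation = segmentation_config(),
                                   epoching = epoching_spec(),
                                   filt = filter_spec()) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    stop_hdemg("invalid_argument", "`n_subjects` must be >= 2")
  }
  if (length(tasks) == 0L || length(efforts) == 0L) {
    stop_hdemg("invalid_argument", "`tasks` and `efforts` must be non-empty")
  }
  effects <- subject_effects(effect_model, n_subjects, seed)
  manifest <- expand.grid(muscle = names(effect_model$muscles),
                          effort = efforts, task = tasks,
                          subject = seq_len(n_subjects),
                          stringsAsFactors = FALSE)[, 4:1]
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rec <- simulate_condition(effect_model, m$subject, m$task, m$effort,
                              m$muscle, effects = effects,
                              n_subjects = n_subjects, seed = seed)
    pr <- process_recording(rec, detector, segmentation, epoching, filt)
    rows[[i]] <- data.frame(subject = m$subject, task = m$task,
                            effort = m$effort, muscle = m$muscle,
                            rms_av_hd = pr$rms_av_hd, rms_av_bip = pr$rms_av_bip,
                            mu_x = pr$mu_x, mu_y = pr$mu_y,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Arrange a feature column for task classification
#'
#' Reshapes the long feature table into one sample per (subject, task,
#' effort) with one column per muscle, plus the class label for the 4-class
#' (task) or 12-class (task x effort) problem.
#'
#' @param features output of [simulate_task_features()].
#' @param value feature column to use (`"rms_av_hd"` or `"rms_av_bip"`).
#' @param labeling `"task"` (4 classes) or `"task_effort"` (12 classes).
#' @return list with `x` (samples x muscles matrix) and `y` (factor labels).
#' @export
task_classification_data <- function(features, value = "rms_av_hd",
                                     labeling = c("task", "task_effort")) {
  labeling <- match.arg(labeling)
  wide <- stats::reshape(
    features[, c("subject", "task", "effort", "muscle", value)],
    idvar = c("subject", "task", "effort"), timevar = "muscle",
    direction = "wide")
  x <- as.matrix(wide[, -(1:3), drop = FALSE])
  y <- if (labeling == "task") wide$task else paste(wide$task, wide$effort, sep = "_")
  list(x = x, y = factor(y))
}
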