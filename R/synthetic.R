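#' Spatial activation blob
#'
#' A 2-D Gaussian component of the target RMS profile over the electrode
#' grid: `peak * exp(-((x-x0)^2/(2*sd_x^2) + (y-y0)^2/(2*sd_y^2)))`, with all
#' lengths in mm (x medial--lateral, y proximal--distal).
#'
#' @param x_mm,y_mm blob centre in mm (electrode (1,1) sits at (0,0)).
#' @param peak peak RMS contribution (signal units, > 0).
#' @param sd_mm spatial standard deviation in mm; length 1 (isotropic) or 2
#'   `(sd_x, sd_y)`.
#' @return an object of class `activation_blob`.
#' @export
activation_blob <- function(x_mm, y_mm, peak, sd_mm) {
  check_scalar_positive(peak, "peak")
  if (length(sd_mm) == 1L) sd_mm <- c(sd_mm, sd_mm)
  if (any(sd_mm <= 0)) stop_hdemg("invalid_argument", "`sd_mm` must be positive")
  structure(list(x_mm = x_mm, y_mm = y_mm, peak = peak, sd_mm = sd_mm),
            class = "activation_blob")
}

#' Target RMS profile of a blob set over a grid
#'
#' @param grid an [electrode_grid()].
#' @param blobs list of [activation_blob()]s (may be empty).
#' @param floor_rms baseline-noise floor added everywhere.
#' @return numeric `n_rows x n_cols` matrix of target RMS values.
#' @export
target_rms_profile <- function(grid, blobs = list(), floor_rms = 0.01) {
  pos <- grid_positions(grid)
  rms <- rep(floor_rms, nrow(pos))
  for (b in blobs) {
    if (!inherits(b, "activation_blob")) {
      stop_hdemg("invalid_argument", "`blobs` must be a list of activation_blob objects")
    }
    rms <- rms + b$peak * exp(-((pos$x_mm - b$x_mm)^2 / (2 * b$sd_mm[1]^2) +
                                (pos$y_mm - b$y_mm)^2 / (2 * b$sd_mm[2]^2)))
  }
  channel_matrix(grid, rms)
}

# band-pass magnitude response of an order-n Butterworth (squared low/high
# prototype product), evaluated at frequencies f
butter_band_mag <- function(f, lo, hi, order = 4) {
  hp <- (f / lo)^(2 * order) / (1 + (f / lo)^(2 * order))
  lp <- 1 / (1 + (f / hi)^(2 * order))
  sqrt(hp * lp)
}

#' Generate a synthetic grid recording
#'
#' Each channel is zero-mean Gaussian noise spectrally shaped by an
#' EMG-band (default 15--350 Hz) Butterworth magnitude response and scaled so
#' its RMS equals the target spatial profile: the sum of the blob profiles at
#' the electrode position plus the baseline floor. The same `(grid, seed)`
#' always yields bit-identical samples.
#'
#' @param grid an [electrode_grid()].
#' @param activation list of [activation_blob()]s; empty list gives a
#'   floor-only (inactive) recording.
#' @param duration_s recording length in seconds (default 3, the analysis
#'   window used throughout).
#' @param fs_hz sampling rate (default 2048).
#' @param floor_rms baseline-noise floor RMS (default 0.01).
#' @param band_hz spectral support of the simulated EMG, `(low, high)` Hz.
#' @param band_order order of the shaping magnitude response (default 6,
#'   keeping at least 95% of the power inside 10--400 Hz).
#' @param seed integer seed.
#' @return a [grid_recording()].
#' @examples
#' g <- electrode_grid(6, 17)
#' blob <- activation_blob(80, 25, peak = 1, sd_mm = 25)
#' rec <- generate_recording(g, list(blob), seed = 1)
#' @export
generate_recording <- function(grid, activation = list(), duration_s = 3,
                               fs_hz = 2048, floor_rms = 0.01,
                               band_hz = c(15, 350), band_order = 6, seed = 1) {
  check_scalar_positive(duration_s, "duration_s")
  check_scalar_positive(fs_hz, "fs_hz")
  n <- round(duration_s * fs_hz)
  target <- target_rms_profile(grid, activation, floor_rms)
  nch <- n_channels(grid)
  samples <- with_seed(seed, {
    white <- matrix(stats::rnorm(nch * n), nrow = n, ncol = nch)
    # frequency-domain shaping by the band-pass magnitude response
    freq <- (seq_len(n) - 1) * fs_hz / n
    fold <- pmin(freq, fs_hz - freq)           # two-sided spectrum
    gain <- butter_band_mag(pmax(fold, 1e-9), band_hz[1], band_hz[2], band_order)
    shaped <- Re(stats::mvfft(stats::mvfft(white) * gain, inverse = TRUE)) / n
    t(shaped)
  })
  # scale each channel to its exact target RMS
  tvec <- as.vector(t(target))                  # channel order (row-major)
  emp <- sqrt(rowMeans(samples^2))
  scale <- ifelse(emp > 0, tvec / emp, 0)
  samples <- samples * scale
  grid_recording(samples, fs_hz, grid,
                 meta = list(target_rms = target, floor_rms = floor_rms,
                             band_hz = band_hz, seed = seed))
}

#' Inject a ground-truth artifact into one channel
#'
#' Emulates the three artifact classes seen in practice on 2-D arrays:
#' `"drift"` adds a high-amplitude low-frequency (< 5 Hz) component,
#' `"powerline"` adds mains interference at 50 Hz and its first four
#' harmonics, and `"isolated_amplitude"` rescales the channel by `severity`
#' (e.g. 0.05 for an isolated low-amplitude contact, 20 for a saturated one).
#' For the additive kinds, `severity` is the ratio of added-component RMS to
#' the channel's current RMS. The injected channel is recorded in the
#' recording's ground-truth `artifacts` table.
#'
#' @param rec a [grid_recording()].
#' @param row,col channel position.
#' @param kind one of `"drift"`, `"powerline"`, `"isolated_amplitude"`.
#' @param severity positive real (see above).
#' @param mains_hz mains frequency for `"powerline"` (default 50).
#' @param seed integer seed (random phases).
#' @return the modified [grid_recording()] with updated `artifacts`.
#' @export
inject_artifact <- function(rec, row, col,
                            kind = c("drift", "powerline", "isolated_amplitude"),
                            severity, mains_hz = 50, seed = 1) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop_hdemg("invalid_argument",
                     sprintf("unknown artifact kind: %s", kind[1])))
  check_scalar_positive(severity, "severity")
  ch <- grid_channel_index(rec$grid, row, col)
  x <- rec$samples[ch, ]
  n <- length(x)
  tt <- (seq_len(n) - 1) / rec$fs_hz
  base_rms <- sqrt(mean(x^2))
  if (base_rms == 0) base_rms <- 1
  add <- switch(kind,
    drift = with_seed(seed, {
      f <- c(1.3, 2.7, 4.1)
      ph <- stats::runif(3, 0, 2 * pi)
      w <- c(1, 0.6, 0.3)
      comp <- colSums(w * t(sapply(seq_along(f), function(i)
        sin(2 * pi * f[i] * tt + ph[i]))))
      comp * severity * base_rms / sqrt(mean(comp^2))
    }),
    powerline = with_seed(seed, {
      f <- mains_hz * (1:5)
      ph <- stats::runif(5, 0, 2 * pi)
      w <- 1 / (1:5)
      comp <- colSums(w * t(sapply(seq_along(f), function(i)
        sin(2 * pi * f[i] * tt + ph[i]))))
      comp * severity * base_rms / sqrt(mean(comp^2))
    }),
    isolated_amplitude = NULL)
  if (kind == "isolated_amplitude") {
    rec$samples[ch, ] <- x * severity
  } else {
    rec$samples[ch, ] <- x + add
  }
  entry <- data.frame(row = row, col = col, kind = kind, severity = severity,
                      stringsAsFactors = FALSE)
  rec$artifacts <- if (is.null(rec$artifacts)) entry else rbind(rec$artifacts, entry)
  rec
}

#' Task / effort / subject effect model for the dataset simulator
#'
#' Defines the study conditions emulated by [simulate_task_dataset()]: one
#' 2-D array per muscle, a co-activation weight per (muscle, task), a linear
#' effort gain (peak RMS scales with %MVC, reaching the co-activation weight
#' at 50% MVC), multiplicative log-normal inter-subject variability, an
#' effort-dependent lateral shift of the activation centre, a per-subject
#' electrode-placement jitter, and a 0--13% rate of injected artifacts.
#'
#' @param muscles named list; each element a list with `grid`
#'   (an [electrode_grid()]), `centre_mm` (blob centre `c(x, y)` in mm) and
#'   `sd_mm` (blob spatial sd, `c(sd_x, sd_y)`).
#' @param coactivation numeric matrix, muscles x tasks, peak RMS (signal
#'   units) at 50% MVC.
#' @param reference_effort %MVC at which the co-activation weight is reached
#'   (gain = effort / reference_effort).
#' @param subject_sdlog sdlog of the log-normal subject multiplier.
#' @param effort_shift_mm named vector: lateral (x) activation-centre shift
#'   per effort level, mm.
#' @param placement_jitter_sd_mm sd of the per-(subject, muscle) electrode
#'   placement error (mm, applied to both axes; 0 disables).
#' @param artifact_rate_range artifact prevalence range per recording
#'   (fraction of channels, drawn uniformly).
#' @param artifact_kinds classes sampled for injected artifacts.
#' @param floor_rms,duration_s,fs_hz passed to [generate_recording()].
#' @return an object of class `task_effect_model`.
#' @export
task_effect_model <- function(
    muscles = NULL,
    coactivation = NULL,
    reference_effort = 50,
    subject_sdlog = 0.25,
    effort_shift_mm = c("10" = 0, "30" = 2.5, "50" = 5),
    placement_jitter_sd_mm = 5,
    artifact_rate_range = c(0, 0.13),
    artifact_kinds = c("drift", "powerline", "isolated_amplitude"),
    floor_rms = 0.01, duration_s = 3, fs_hz = 2048) {
  if (is.null(muscles)) {
    upper <- function() electrode_grid(8, 15, origin_row = 4, origin_col = 8,
                                       circumference_mm = 300, segment_length_mm = 320)
    fore  <- function() electrode_grid(6, 17, origin_row = 3, origin_col = 9,
                                       circumference_mm = 260, segment_length_mm = 250)
    muscles <- list(
      biceps          = list(grid = upper(), centre_mm = c(70, 35), sd_mm = c(28, 45)),
      triceps         = list(grid = upper(), centre_mm = c(70, 35), sd_mm = c(28, 45)),
      brachioradialis = list(grid = fore(),  centre_mm = c(80, 25), sd_mm = c(30, 40)),
      anconeus        = list(grid = fore(),  centre_mm = c(80, 25), sd_mm = c(30, 40)),
      pronator_teres  = list(grid = fore(),  centre_mm = c(80, 25), sd_mm = c(30, 40)))
  }
  if (is.null(coactivation)) {
    coactivation <- rbind(
      biceps          = c(flexion = 1.00, extension = 0.15, pronation = 0.10, supination = 0.80),
      triceps         = c(flexion = 0.15, extension = 1.00, pronation = 0.10, supination = 0.10),
      brachioradialis = c(flexion = 0.90, extension = 0.30, pronation = 0.60, supination = 0.50),
      anconeus        = c(flexion = 0.40, extension = 0.90, pronation = 0.80, supination = 0.80),
      pronator_teres  = c(flexion = 0.40, extension = 0.30, pronation = 1.00, supination = 0.30))
  }
  structure(list(muscles = muscles, coactivation = coactivation,
                 reference_effort = reference_effort,
                 subject_sdlog = subject_sdlog,
                 effort_shift_mm = effort_shift_mm,
                 placement_jitter_sd_mm = placement_jitter_sd_mm,
                 artifact_rate_range = artifact_rate_range,
                 artifact_kinds = artifact_kinds,
                 floor_rms = floor_rms, duration_s = duration_s, fs_hz = fs_hz),
            class = "task_effect_model")
}

# deterministic per-(subject, muscle) placement jitter and subject gain
subject_effects <- function(model, n_subjects, seed) {
  mnames <- names(model$muscles)
  with_seed(derive_seed(seed, 0L), {
    gain <- matrix(stats::rlnorm(n_subjects * length(mnames),
                                 meanlog = -model$subject_sdlog^2 / 2,
                                 sdlog = model$subject_sdlog),
                   n_subjects, length(mnames), dimnames = list(NULL, mnames))
    jit_x <- matrix(stats::rnorm(n_subjects * length(mnames), 0,
                                 model$placement_jitter_sd_mm),
                    n_subjects, length(mnames), dimnames = list(NULL, mnames))
    jit_y <- matrix(stats::rnorm(n_subjects * length(mnames), 0,
                                 model$placement_jitter_sd_mm),
                    n_subjects, length(mnames), dimnames = list(NULL, mnames))
    list(gain = gain, jit_x = jit_x, jit_y = jit_y)
  })
}

#' Simulate one (subject, task, effort, muscle) recording
#'
#' @param model a [task_effect_model()].
#' @param subject,task,effort condition identifiers (`subject` integer,
#'   `task` a column of the co-activation matrix, `effort` %MVC).
#' @param muscle name of the muscle array.
#' @param effects internal per-subject effects table (from the dataset
#'   simulator); computed on the fly when `NULL`.
#' @param n_subjects total number of subjects (for the effects table).
#' @param seed base seed of the dataset.
#' @return a [grid_recording()] with ground-truth `artifacts` and condition
#'   metadata in `meta`.
#' @export
simulate_condition <- function(model, subject, task, effort, muscle,
                               effects = NULL, n_subjects = max(subject), seed = 1) {
  if (is.null(effects)) effects <- subject_effects(model, n_subjects, seed)
  mu <- model$muscles[[muscle]]
  if (is.null(mu)) stop_hdemg("invalid_argument", sprintf("unknown muscle '%s'", muscle))
  w <- model$coactivation[muscle, task]
  gain <- effort / model$reference_effort
  shift <- model$effort_shift_mm[as.character(effort)]
  if (is.na(shift)) shift <- 0
  peak <- w * gain * effects$gain[subject, muscle]
  centre <- mu$centre_mm + c(shift, 0) +
    c(effects$jit_x[subject, muscle], effects$jit_y[subject, muscle])
  blob <- activation_blob(centre[1], centre[2], peak = max(peak, 1e-6),
                          sd_mm = mu$sd_mm)
  cseed <- derive_seed(seed, 7L * subject + 131L * match(muscle, names(model$muscles)) +
                         1009L * match(task, colnames(model$coactivation)) +
                         13L * effort)
  rec <- generate_recording(mu$grid, list(blob), duration_s = model$duration_s,
                            fs_hz = model$fs_hz, floor_rms = model$floor_rms,
                            seed = cseed)
  # inject ground-truth artifacts at a prevalence drawn from the study range
  rec <- with_seed(derive_seed(cseed, 3L), {
    rate <- stats::runif(1, model$artifact_rate_range[1], model$artifact_rate_range[2])
    n_art <- round(rate * n_channels(mu$grid))
    if (n_art > 0L) {
      idx <- sample.int(n_channels(mu$grid), n_art)
      kinds <- sample(model$artifact_kinds, n_art, replace = TRUE)
      for (i in seq_len(n_art)) {
        r <- (idx[i] - 1L) %/% mu$grid$n_cols + 1L
        c <- (idx[i] - 1L) %% mu$grid$n_cols + 1L
        sev <- switch(kinds[i], drift = stats::runif(1, 3, 8),
                      powerline = stats::runif(1, 3, 8),
                      isolated_amplitude = stats::runif(1, 0.02, 0.1))
        rec <- inject_artifact(rec, r, c, kinds[i], sev,
                               seed = derive_seed(cseed, 100L + i))
      }
    }
    rec
  })
  rec$meta$condition <- list(subject = subject, task = task, effort = effort,
                             muscle = muscle)
  rec
}

#' Simulate a full task / effort / subject dataset
#'
#' Generates, per (subject, task, effort), one recording for each muscle
#' array, with blob peaks scaled by the task co-activation weight times a
#' linear effort gain, log-normal inter-subject multipliers, an
#' effort-dependent lateral centre shift and per-subject placement jitter.
#'
#' Note the returned list holds every recording in memory; for full-size
#' datasets prefer [simulate_task_features()], which processes conditions one
#' at a time.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param tasks,efforts condition levels (non-empty).
#' @param effect_model a [task_effect_model()].
#' @param seed integer seed.
#' @return list with elements `records` (list of [grid_recording()]s, one per
#'   subject x task x effort x muscle) and `manifest` (data.frame of
#'   conditions in the same order).
#' @export
simulate_task_dataset <- function(n_subjects = 12,
                                  tasks = c("flexion", "extension", "pronation", "supination"),
                                  efforts = c(10, 30, 50),
                                  effect_model = task_effect_model(),
                                  seed = 1) {
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
  records <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    records[[i]] <- simulate_condition(effect_model, m$subject, m$task, m$effort,
                                       m$muscle, effects = effects,
                                       n_subjects = n_subjects, seed = seed)
  }
  list(records = records, manifest = manifest)
}
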