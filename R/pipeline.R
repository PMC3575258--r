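#' Run the full map pipeline over a set of recordings
#'
#' Executes the stages in order for every input recording — detection
#' features, artifact classification, activation map, replacement of flagged
#' channels, h-dome segmentation, coordinate normalisation, projections —
#' then assembles the condition feature table and, when several subjects
#' share a condition grid, the inter-subject average and variability maps.
#' Every stage is logged with its parameters and timing; results are written
#' under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param recordings list of [grid_recording()]s (each may carry condition
#'   metadata in `meta$condition`) or paths readable by [read_recording()].
#' @param out_dir output directory (created if missing).
#' @param verbose log stage messages (default `TRUE`).
#' @return invisibly, the feature table data.frame.
#' @export
run_pipeline <- function(config, recordings, out_dir, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) {
    stop_hdemg("invalid_argument", "`config` must be a pipeline_config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop_hdemg("stage_error",
                 sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    log_msg("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    out
  }
  rows <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    if (is.character(rec)) rec <- stage("read", read_recording(rec))
    cond <- rec$meta$condition %||%
      list(subject = i, task = NA_character_, effort = NA_real_,
           muscle = sprintf("array%02d", i))
    tag <- sprintf("s%02d_%s_%s_%s", cond$subject, cond$task, cond$effort,
                   cond$muscle)
    log_msg("processing %s (%d/%d)", tag, i, length(recordings))
    pr <- stage(paste0("process:", tag),
                process_recording(rec, config$detector, config$segmentation,
                                  config$epoching, config$filter))
    stage(paste0("write:", tag), {
      write_qc_report(pr$features, pr$mask, file.path(out_dir, paste0(tag, "_qc.tsv")))
      write_map(pr$map, file.path(out_dir, paste0(tag, "_map.tsv")))
      utils::write.table(
        data.frame(label = as.vector(t(pr$seg$labels))),
        file.path(out_dir, paste0(tag, "_labels.tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    })
    rows[[i]] <- data.frame(subject = cond$subject, task = cond$task,
                            effort = cond$effort, muscle = cond$muscle,
                            rms_av_hd = pr$rms_av_hd, rms_av_bip = pr$rms_av_bip,
                            mu_x = pr$mu_x, mu_y = pr$mu_y,
                            stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  utils::write.table(features, file.path(out_dir, "features.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  log_msg("wrote %d feature rows to %s", nrow(features),
          file.path(out_dir, "features.csv"))
  invisible(features)
}
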