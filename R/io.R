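# Plain-text interchange: sessions, step tables, decision datasets, window
# predictions and model results as CSV/JSON.

#' Write / read a session as CSV files
#'
#' Writes `tracking.csv` (frame, view, landmark, x, y, confidence; for the
#' top/side view `y` is the vertical coordinate, for the bottom view the
#' lateral one), `wheel.csv` (frame, displacement_mm) and `trials.csv`
#' (trial, obstacle_height_mm, engage_position_m, light, condition, ...).
#'
#' @param session An `obs_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "obs_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$tracking, file.path(dir, "tracking.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(frame = seq_along(session$wheel),
                              displacement_mm = session$wheel,
                              frame_rate = session$frame_rate),
                   file.path(dir, "wheel.csv"), row.names = FALSE)
  if (!is.null(session$trials))
    utils::write.csv(session$trials, file.path(dir, "trials.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(dir) {
  tk <- utils::read.csv(file.path(dir, "tracking.csv"))
  wh <- utils::read.csv(file.path(dir, "wheel.csv"))
  trials_path <- file.path(dir, "trials.csv")
  trials <- if (file.exists(trials_path)) utils::read.csv(trials_path) else NULL
  structure(list(tracking = tk,
                 wheel = wh$displacement_mm,
                 trials = trials,
                 frame_rate = wh$frame_rate[1],
                 n_frames = nrow(wh)),
            class = "obs_session")
}

#' Write / read a step table as CSV
#'
#' @param steps A `step_table`.
#' @param path Output file.
#' @export
write_steps_csv <- function(steps, path) {
  utils::write.csv(as.data.frame(steps), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_steps_csv
#' @export
read_steps_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("step_table", "data.frame")
  out
}

#' Write a decision dataset as CSV
#'
#' One row per trial: the eight features, predicted and actual landing
#' distances, label, exclusion code and identifiers.
#' @param data A `decision_dataset`.
#' @param path Output file.
#' @export
write_decision_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decision_csv
#' @export
read_decision_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("decision_dataset", "data.frame")
  out
}

#' Write decision-model results as JSON
#'
#' Serialises model weights, fold accuracies and (optionally) a forward
#' selection path.
#'
#' @param model A `decision_glm`.
#' @param path Output file.
#' @param selection Optional `selection_path`.
#' @export
write_model_json <- function(model, path, selection = NULL) {
  out <- list(coefficients = as.list(model$coefficients),
              fold_accuracy = model$fold_accuracy,
              mean_accuracy = model$mean_accuracy,
              class_weights = as.list(model$class_weights),
              n_per_class = as.list(model$n_per_class),
              folds = model$folds, features = model$features)
  if (!is.null(selection)) out$selection_path <- as.data.frame(selection)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a conditional landing heatmap as CSV
#'
#' Columns are predicted-landing bins, rows actual-landing bins.
#' @param heatmap A `landing_heatmap`.
#' @param path Output file.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  m <- unclass(heatmap)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Write / read window prediction streams as CSV
#'
#' @param stream Data frame `window_start`, `p1` ... `p11`.
#' @param path File path.
#' @export
write_window_stream_csv <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_stream_csv
#' @export
read_window_stream_csv <- function(path) {
  utils::read.csv(path)
}

#' Write a consensus result as JSON
#'
#' @param result A `consensus_result`.
#' @param path Output file.
#' @export
write_consensus_json <- function(result, path) {
  out <- list(frame = result$frame, margin = result$margin,
              votes = as.list(result$votes))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
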