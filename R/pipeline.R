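# Convenience orchestration: from a simulated session to step tables,
# landing models and decision datasets.

#' Run the kinematic pipeline on a simulated session
#'
#' QC, un-head-fixing, stance/step segmentation and obstacle-step annotation
#' in one call.
#'
#' @param gs Output of [generate_session()] (or an `obs_session`).
#' @param qc,stance_cfg Configurations for [apply_qc()] and [detect_stance()].
#' @return List with `kin` (world-frame kinematics) and `steps` (annotated
#'   `step_table`).
#' @export
session_pipeline <- function(gs, qc = qc_config(), stance_cfg = stance_config()) {
  session <- if (inherits(gs, "obs_session")) gs else gs$session
  kin <- unheadfix(apply_qc(session, qc))
  steps <- step_table(kin, stance_cfg)
  ann <- annotate_obstacle_steps(steps, kin)
  list(kin = kin, steps = ann$steps, heights = ann$heights)
}

#' Pooled forepaw control steps of a session
#'
#' The two latest steps of each forepaw before each trial's whisker contact,
#' pooled over trials (duplicates removed).
#'
#' @param steps A `step_table`.
#' @param contact_frames Per-trial contact frames.
#' @param paws Paws to include.
#' @return A `step_table` of control steps.
#' @export
session_control_steps <- function(steps, contact_frames,
                                  paws = c("LF", "RF")) {
  out <- do.call(rbind, lapply(contact_frames, function(cf) {
    if (is.na(cf)) return(NULL)
    do.call(rbind, lapply(paws, function(p)
      suppressWarnings(control_steps(steps, cf, p))))
  }))
  if (is.null(out)) return(empty_step_table())
  out <- out[!duplicated(out[, c("paw", "lift_off_frame")]), ]
  class(out) <- c("step_table", "data.frame")
  out
}

#' Simulate a session and assemble its decision dataset
#'
#' Generates a session, runs the kinematic pipeline, fits the per-paw landing
#' models on control steps, and labels every trial. Whisker-contact frames
#' are taken from the simulation ground truth (standing in for the
#' whisker-camera contact detector).
#'
#' @param config A [gait_config()].
#' @param seed Session seed.
#' @param mouse,condition Identifiers.
#' @return A `decision_dataset` with attributes `"landing_model"`,
#'   `"control_steps"` and `"truth"`.
#' @export
simulate_decision_dataset <- function(config = gait_config(), seed = 1L,
                                      mouse = NA, condition = NA) {
  gs <- generate_session(config, seed)
  pl <- session_pipeline(gs)
  contacts <- gs$truth$trials$contact_frame
  ctrl <- session_control_steps(pl$steps, contacts)
  lmod <- fit_landing_model(ctrl, paws = c("LF", "RF"), session = seed)
  dd <- decision_dataset(pl$kin, pl$steps, contacts, lmod,
                         mouse = mouse, condition = condition)
  attr(dd, "landing_model") <- lmod
  attr(dd, "control_steps") <- ctrl
  attr(dd, "truth") <- gs$truth
  dd
}

#' Simulate a multi-session mouse and pool its decision trials
#'
#' @param config A [gait_config()].
#' @param seeds One seed per session.
#' @param mouse Identifier.
#' @return Pooled `decision_dataset`.
#' @export
simulate_mouse <- function(config = gait_config(), seeds = 1:3, mouse = "m1") {
  out <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    d <- simulate_decision_dataset(config, seeds[i], mouse = mouse)
    d$trial <- d$trial + (i - 1L) * 10000L
    attributes(d)[c("landing_model", "control_steps", "truth")] <- NULL
    as.data.frame(d)
  }))
  class(out) <- c("decision_dataset", "data.frame")
  out
}
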