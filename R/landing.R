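# Speed-based landing-position models and whisker-contact imputation.

#' Fit per-paw linear models of step length on running speed
#'
#' Step lengths are strongly correlated with running speed, which allows the
#' landing position of a step to be predicted from the wheel speed and the
#' lift-off position. One ordinary-least-squares fit per paw of step length on
#' per-step wheel speed, trained on control steps.
#'
#' @param steps A `step_table` of control steps (must contain `speed`).
#' @param paws Paws to fit (default: every paw present).
#' @param session Session identifier used in error messages and stored in the
#'   result.
#' @param min_steps Minimum control steps per paw.
#' @param holdout If `TRUE`, report leave-one-out mean absolute error instead
#'   of the in-sample MAE.
#' @return Object of class `landing_model`: per paw, intercept (mm), slope
#'   (mm per m/s), `mae` (mm) and `n`.
#' @export
fit_landing_model <- function(steps, paws = NULL, session = NA,
                              min_steps = 10, holdout = FALSE) {
  if (is.null(paws)) paws <- unique(steps$paw)
  fits <- list()
  for (p in paws) {
    s <- steps[steps$paw == p & !is.na(steps$speed) & !is.na(steps$length), ]
    if (nrow(s) < max(2, min_steps) && nrow(s) != 2)
      stop(sprintf("insufficient control steps for paw %s in session %s (%d < %d)",
                   p, session, nrow(s), min_steps))
    fit <- stats::lm(length ~ speed, data = s)
    res <- stats::residuals(fit)
    if (holdout) {
      h <- stats::hatvalues(fit)
      res <- res / (1 - h)
    }
    fits[[p]] <- list(intercept = unname(stats::coef(fit)[1]),
                      slope = unname(stats::coef(fit)[2]),
                      mae = mean(abs(res)),
                      r = if (stats::sd(s$speed) > 0 && stats::sd(s$length) > 0)
                        stats::cor(s$speed, s$length) else NA_real_,
                      n = nrow(s),
                      low_n = nrow(s) < min_steps)
  }
  structure(list(paws = fits, session = session, holdout = holdout),
            class = "landing_model")
}

#' @export
print.landing_model <- function(x, ...) {
  cat("<landing_model>", if (!is.na(x$session)) paste("session", x$session), "\n")
  for (p in names(x$paws)) {
    f <- x$paws[[p]]
    cat(sprintf("  %s: length = %.2f + %.1f * speed  (MAE %.2f mm, r %.3f, n %d)%s\n",
                p, f$intercept, f$slope, f$mae, f$r, f$n,
                if (f$low_n) " [low n]" else ""))
  }
  invisible(x)
}

#' @export
coef.landing_model <- function(object, ...) {
  t(vapply(object$paws, function(f) c(intercept = f$intercept, slope = f$slope),
           numeric(2)))
}

#' Predict step length for a paw at a given wheel speed
#'
#' @param object A `landing_model`.
#' @param paw Paw name.
#' @param speed Wheel speed(s), m/s.
#' @param ... Unused.
#' @return Predicted step length(s), mm.
#' @export
predict.landing_model <- function(object, paw, speed, ...) {
  f <- object$paws[[paw]]
  if (is.null(f)) stop(sprintf("no landing model for paw %s", paw))
  f$intercept + f$slope * speed
}

#' Predicted landing distance of the paw in swing at whisker contact
#'
#' Where the paw would land, relative to the obstacle, if no modifications
#' were made: lift-off position plus the speed-predicted step length, minus
#' the obstacle position. Negative values mean the paw would land in front of
#' the obstacle.
#'
#' @param lift_off_x Lift-off position (mm, world frame); `NA` when the paw
#'   was already in swing at the start of the observation (the trial is then
#'   excluded).
#' @param speed Wheel speed at contact (m/s).
#' @param obstacle_x Obstacle position (mm, world frame).
#' @param model A `landing_model`.
#' @param paw Paw name.
#' @return Predicted landing distance(s), mm (`NA` if `lift_off_x` missing).
#' @export
predict_landing_distance <- function(lift_off_x, speed, obstacle_x, model, paw) {
  lift_off_x + predict(model, paw, speed) - obstacle_x
}

#' Model of whisker-contact position versus running speed
#'
#' For whisker-trimmed sessions the moment of (would-be) whisker contact is
#' imputed from a per-mouse linear model of contact position (mm anterior of
#' the nose) on trial running speed, fit on whisker-present sessions.
#'
#' @param contact_position Observed contact positions (mm anterior of nose).
#' @param speed Trial running speeds (m/s).
#' @return Object of class `contact_model`.
#' @export
contact_position_model <- function(contact_position, speed) {
  ok <- stats::complete.cases(contact_position, speed)
  if (sum(ok) < 2) stop("need at least 2 whisker-present trials to fit a contact model")
  fit <- stats::lm(contact_position[ok] ~ speed[ok])
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 speed_range = range(speed[ok]),
                 r = if (stats::sd(speed[ok]) > 0)
                   stats::cor(speed[ok], contact_position[ok]) else NA_real_,
                 n = sum(ok)),
            class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("<contact_model> position = %.2f + %.2f * speed (r %.2f, n %d)\n",
              x$intercept, x$slope, x$r, x$n))
  invisible(x)
}

#' Impute whisker-contact frames for a whisker-trimmed session
#'
#' For each trial, predicts the contact position from the trial running speed
#' with a [contact_position_model()] and returns the first frame at which the
#' obstacle reaches that position relative to the nose.
#'
#' @param kin World-frame `obs_kinematics` with a `trials` table.
#' @param model A `contact_position_model()` fit on whisker-present sessions
#'   of the same mouse.
#' @return Data frame `trial`, `imputed_contact_frame`, `predicted_position`,
#'   `speed`, `extrapolated` (speed outside the training range; prediction is
#'   an extrapolation and flagged with a warning).
#' @export
impute_contact_time <- function(kin, model) {
  stopifnot(inherits(model, "contact_model"), kin$frame_tag == "world")
  tr <- kin$trials
  obs <- trial_obstacle_positions(kin)
  nose_x <- kin$positions[, "x", "nose"]
  out <- lapply(seq_len(nrow(tr)), function(i) {
    e <- tr$engage_frame[i]
    w <- e:min(e + 1000L, kin$n_frames)
    sp <- mean(kin$wheel_velocity[e:min(e + 50L, kin$n_frames)])
    pos <- model$intercept + model$slope * sp
    hit <- which(obs$obstacle_x[i] - nose_x[w] <= pos)
    data.frame(trial = tr$trial[i],
               imputed_contact_frame = if (length(hit)) w[hit[1]] else NA_integer_,
               predicted_position = pos, speed = sp,
               extrapolated = sp < model$speed_range[1] | sp > model$speed_range[2])
  })
  out <- do.call(rbind, out)
  if (any(out$extrapolated))
    warning(sprintf("%d trial(s) outside the contact model's speed range; extrapolated",
                    sum(out$extrapolated)))
  out
}
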