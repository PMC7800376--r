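#' Simulation configuration for synthetic running-wheel sessions
#'
#' Builds the parameter set that drives [generate_session()]. Defaults describe
#' a head-fixed mouse trotting on a wheel at 250 Hz while cylindrical obstacles
#' approach at wheel speed: step length follows a linear speed law
#' `length = a + b * speed` with Gaussian residuals, obstacle geometry is
#' jittered uniformly, whisker contact occurs a fixed reach in front of the
#' nose (with speed-dependent jitter), and on each trial the forepaw in swing
#' at contact is shortened or lengthened according to a logistic rule on the
#' predicted landing distance.
#'
#' @param frame_rate Video frame rate in Hz.
#' @param n_trials Number of obstacle trials per session.
#' @param mean_speed,speed_sd Mean and stationary standard deviation of the
#'   per-stride wheel speed (m/s). Speeds follow a stride-level AR(1) process.
#' @param step_length_slope,step_length_intercept Slope `b` (mm per m/s) and
#'   intercept `a` (mm) of the step-length versus speed law.
#' @param landing_noise_sd Standard deviation (mm) of the step-length residual
#'   around the speed law. Internally paw placements get independent noise of
#'   `landing_noise_sd / sqrt(2)` so the marginal step-length residual has the
#'   requested SD without paw positions drifting relative to the body.
#' @param duty_factor Fraction of the stride cycle a limb spends in stance.
#' @param obstacle_height_range Inclusive range (mm) for the uniformly drawn
#'   obstacle height.
#' @param engage_distances Wheel distances (m) after each reward at which the
#'   obstacles start moving; each jittered by `engage_jitter`.
#' @param engage_jitter Half-width (m) of the uniform jitter on engage
#'   positions.
#' @param obstacle_start_distance Distance (m) of the obstacle from the nose
#'   when it engages; jittered by `obstacle_start_jitter` (m).
#' @param obstacle_start_jitter Half-width (m) of the start-distance jitter.
#' @param obstacle_diameter Obstacle diameter (mm).
#' @param light_on_probability Probability that the obstacle is illuminated.
#' @param decision_threshold Landing-distance threshold `theta` (mm, relative
#'   to the obstacle; negative = in front) at which shortening and lengthening
#'   are equally likely for a zero-height obstacle.
#' @param decision_height_coefficient Shift of the threshold (mm per mm of
#'   obstacle height); positive values make lengthening less likely for high
#'   obstacles.
#' @param decision_temperature Logit scale `tau` (mm) of the planted decision
#'   rule. The default is calibrated with [calibrate_decision_temperature()] so
#'   that the rule's Bayes accuracy on the default trial distribution is 0.73.
#' @param planted_latency Reaction latency (ms) between whisker contact and
#'   the onset of the kinematic modification.
#' @param whisker_reach Distance (mm) anterior of the nose at which whisker
#'   contact occurs.
#' @param contact_speed_slope Dependence of the contact position on running
#'   speed (mm per m/s); together with `contact_noise_sd` this is calibrated so
#'   the contact-position/speed correlation is about 0.27.
#' @param contact_noise_sd Trial-to-trial SD (mm) of the contact position.
#' @param whiskers_present If `FALSE` the session emulates whisker trimming:
#'   no contact events are observable, the decision temperature is multiplied
#'   by `whiskerless_temperature_factor` and landing noise is inflated by
#'   `whiskerless_noise_factor`, producing the diffuse landing distributions
#'   seen without whisker input.
#' @param whiskerless_temperature_factor,whiskerless_noise_factor Degradation
#'   factors applied when `whiskers_present = FALSE`.
#' @param confidence_drop_rate,jump_rate,cross_view_rate,gap_rate Artifact
#'   rates (per frame and landmark) used by [inject_tracking_artifacts()].
#' @param jump_size Range (mm) of injected single-frame jump magnitudes.
#' @param max_gap Maximum length (frames) of injected tracking gaps.
#' @param nose_offset Anterior offset (mm) of the nose from the body reference.
#' @param paw_home_fore,paw_home_hind Home touchdown positions (mm) of fore and
#'   hind paws relative to the body reference.
#' @param swing_peak_height,swing_peak_sd Swing apex (mm) of an unobstructed
#'   step at the mean speed, and its trial-to-trial SD. The apex scales with
#'   step length times swing duration, so faster, longer steps are also
#'   higher.
#' @param clearance_margin,clearance_sd Mean and SD (mm) of the extra height by
#'   which paws clear the obstacle.
#' @param modification_delta Range (mm) of the step shortening/lengthening
#'   magnitude relative to the predicted landing position.
#' @param speed_ar Stride-to-stride autocorrelation of wheel speed.
#' @param body_angle_sd,tail_height_mean,tail_height_sd Stationary parameters
#'   of the AR(1) body-angle (degrees) and tail-height (mm) processes.
#' @param reward_distance Wheel distance (m) between rewards (one lap of the
#'   trial schedule).
#'
#' @return An object of class `gait_config` (a validated list).
#' @export
gait_config <- function(frame_rate = 250,
                        n_trials = 65,
                        mean_speed = 0.55,
                        speed_sd = 0.10,
                        step_length_slope = 107,
                        step_length_intercept = -3.7,
                        landing_noise_sd = 6.9,
                        duty_factor = 0.6,
                        obstacle_height_range = c(4, 10),
                        engage_distances = c(0.9, 2.7, 4.5),
                        engage_jitter = 0.1,
                        obstacle_start_distance = 0.31,
                        obstacle_start_jitter = 0.015,
                        obstacle_diameter = 3.175,
                        light_on_probability = 0.5,
                        decision_threshold = -10,
                        decision_height_coefficient = 1.0,
                        decision_temperature = 6.15,
                        planted_latency = 24,
                        whisker_reach = 15,
                        contact_speed_slope = 7.4,
                        contact_noise_sd = 1.75,
                        whiskers_present = TRUE,
                        whiskerless_temperature_factor = 3,
                        whiskerless_noise_factor = 1.5,
                        confidence_drop_rate = 0.01,
                        jump_rate = 0.002,
                        cross_view_rate = 0.005,
                        gap_rate = 0.001,
                        jump_size = c(20, 40),
                        max_gap = 4,
                        nose_offset = 30,
                        paw_home_fore = 28.5,
                        paw_home_hind = -25,
                        swing_peak_height = 10,
                        swing_peak_sd = 0.6,
                        clearance_margin = 4,
                        clearance_sd = 0.8,
                        modification_delta = c(5, 15),
                        speed_ar = 0.8,
                        body_angle_sd = 3,
                        tail_height_mean = 10,
                        tail_height_sd = 2,
                        reward_distance = 5.4) {
  cfg <- as.list(environment())
  class(cfg) <- "gait_config"
  validate_gait_config(cfg)
  cfg
}

validate_gait_config <- function(cfg) {
  chk <- function(field, ok, msg) if (!ok) stop_config(field, msg)
  chk("frame_rate", is_scalar_num(cfg$frame_rate) && cfg$frame_rate > 0, "must be > 0")
  chk("n_trials", is_scalar_num(cfg$n_trials) && cfg$n_trials >= 1, "must be >= 1")
  chk("mean_speed", is_scalar_num(cfg$mean_speed) && cfg$mean_speed > 0, "must be > 0")
  chk("speed_sd", is_scalar_num(cfg$speed_sd) && cfg$speed_sd >= 0, "must be >= 0")
  chk("landing_noise_sd", is_scalar_num(cfg$landing_noise_sd) && cfg$landing_noise_sd >= 0,
      "must be >= 0")
  chk("duty_factor", is_scalar_num(cfg$duty_factor) &&
        cfg$duty_factor > 0 && cfg$duty_factor < 1, "must lie in (0, 1)")
  chk("obstacle_height_range", is.numeric(cfg$obstacle_height_range) &&
        length(cfg$obstacle_height_range) == 2L &&
        cfg$obstacle_height_range[1] <= cfg$obstacle_height_range[2] &&
        cfg$obstacle_height_range[1] > 0, "must be an increasing positive pair")
  chk("decision_temperature", is_scalar_num(cfg$decision_temperature) &&
        cfg$decision_temperature > 0, "must be > 0")
  chk("planted_latency", is_scalar_num(cfg$planted_latency) && cfg$planted_latency >= 0,
      "must be >= 0")
  chk("light_on_probability", is_scalar_num(cfg$light_on_probability) &&
        cfg$light_on_probability >= 0 && cfg$light_on_probability <= 1,
      "must lie in [0, 1]")
  for (f in c("confidence_drop_rate", "jump_rate", "cross_view_rate", "gap_rate")) {
    chk(f, is_scalar_num(cfg[[f]]) && cfg[[f]] >= 0 && cfg[[f]] <= 1,
        "must lie in [0, 1]")
  }
  chk("whisker_reach", is_scalar_num(cfg$whisker_reach) && cfg$whisker_reach > 0,
      "must be > 0")
  chk("step_length_slope", is_scalar_num(cfg$step_length_slope) &&
        cfg$step_length_slope > 0, "must be > 0")
  invisible(cfg)
}

#' @export
print.gait_config <- function(x, ...) {
  cat("<gait_config>\n")
  cat(sprintf("  %d trials @ %g Hz; speed %.2f +- %.2f m/s; step length = %.1f + %.0f * v mm (sd %.1f)\n",
              x$n_trials, x$frame_rate, x$mean_speed, x$speed_sd,
              x$step_length_intercept, x$step_length_slope, x$landing_noise_sd))
  cat(sprintf("  obstacles %g-%g mm; decision theta = %g mm, height coef %g, tau = %g mm; latency %g ms\n",
              x$obstacle_height_range[1], x$obstacle_height_range[2],
              x$decision_threshold, x$decision_height_coefficient,
              x$decision_temperature, x$planted_latency))
  cat(sprintf("  whiskers %s; reach %g mm\n",
              if (x$whiskers_present) "present" else "trimmed", x$whisker_reach))
  invisible(x)
}

#' Tracking quality-control configuration
#'
#' Thresholds for [apply_qc()]. The pipeline masks low-confidence samples,
#' single-frame jumps, and cross-view x disagreements, de-spikes with a
#' 3-frame temporal median, and linearly interpolates masked values.
#'
#' @param confidence_threshold Samples with tracking confidence strictly below
#'   this value are masked.
#' @param velocity_jump_threshold Maximum plausible frame-to-frame displacement
#'   (mm/frame); isolated samples jumping further on both sides are masked.
#' @param median_window Window (frames, odd) of the temporal median.
#' @param median_spike_tol Only samples deviating from the window median by
#'   more than this (mm) are replaced; the default sits above genuine
#'   single-frame kinematic excursions at 250 Hz but below jump artifacts.
#'   Ignored when `median_mode = "full"`.
#' @param median_mode `"despike"` (replace outliers only, the default) or
#'   `"full"` (classic median filter).
#' @param cross_view_x_tolerance Maximum allowed |x_top - x_bottom| (mm).
#' @param max_masked_fraction A landmark with more than this fraction of
#'   frames masked triggers a QC failure.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(confidence_threshold = 0.99,
                      velocity_jump_threshold = 15,
                      median_window = 3,
                      median_spike_tol = 10,
                      median_mode = c("despike", "full"),
                      cross_view_x_tolerance = 5,
                      max_masked_fraction = 0.5) {
  median_mode <- match.arg(median_mode)
  if (!is_scalar_num(confidence_threshold) || confidence_threshold <= 0)
    stop_config("confidence_threshold", "must be > 0")
  if (!is_scalar_num(velocity_jump_threshold) || velocity_jump_threshold <= 0)
    stop_config("velocity_jump_threshold", "must be > 0")
  if (!is_scalar_num(median_window) || median_window < 1 || median_window %% 2 != 1)
    stop_config("median_window", "must be a positive odd integer")
  if (!is_scalar_num(cross_view_x_tolerance) || cross_view_x_tolerance <= 0)
    stop_config("cross_view_x_tolerance", "must be > 0")
  structure(list(confidence_threshold = confidence_threshold,
                 velocity_jump_threshold = velocity_jump_threshold,
                 median_window = median_window,
                 median_spike_tol = median_spike_tol,
                 median_mode = median_mode,
                 cross_view_x_tolerance = cross_view_x_tolerance,
                 max_masked_fraction = max_masked_fraction),
            class = "qc_config")
}

#' Stance-detection configuration
#'
#' A paw is in stance when its world-frame horizontal speed is within
#' `velocity_tolerance` of zero (equivalently, camera-frame speed within the
#' tolerance of the wheel-surface speed) and its height is within
#' `height_tolerance` of the wheel surface; the frame-wise call is then
#' debounced with a `debounce`-ms median filter.
#'
#' @param velocity_tolerance m/s.
#' @param height_tolerance mm above the wheel surface.
#' @param debounce ms; converted to the nearest odd number of frames.
#' @return An object of class `stance_config`.
#' @export
stance_config <- function(velocity_tolerance = 0.2,
                          height_tolerance = 5,
                          debounce = 20) {
  for (f in c("velocity_tolerance", "height_tolerance", "debounce")) {
    v <- get(f)
    if (!is_scalar_num(v) || v <= 0) stop_config(f, "must be > 0")
  }
  structure(list(velocity_tolerance = velocity_tolerance,
                 height_tolerance = height_tolerance,
                 debounce = debounce),
            class = "stance_config")
}

# debounce window in frames (odd)
debounce_frames <- function(cfg, frame_rate) {
  w <- round(cfg$debounce / 1000 * frame_rate)
  w <- max(1L, as.integer(w))
  if (w %% 2L == 0L) w <- w + 1L
  w
}

#' Reaction-time estimation configuration
#'
#' @param k Number of matched control steps in the kNN family.
#' @param deviation_threshold Onset threshold in family standard deviations.
#' @param sustain Number of consecutive supra-threshold frames required.
#' @param sd_floor Lower bound (mm) on the per-frame family SD, preventing
#'   division blow-ups in low-variance (e.g. stance) frames.
#' @param mid_swing_fraction Trials are retained when contact falls in the
#'   central fraction of the swing.
#' @param post_window Frames past contact over which the deviation trace is
#'   evaluated.
#' @return An object of class `reaction_config`.
#' @export
reaction_config <- function(k = 40,
                            deviation_threshold = 2.5,
                            sustain = 2,
                            sd_floor = 0.1,
                            mid_swing_fraction = 0.6,
                            post_window = 16) {
  if (!is_scalar_num(k) || k < 2) stop_config("k", "must be >= 2")
  if (!is_scalar_num(deviation_threshold) || deviation_threshold < 0)
    stop_config("deviation_threshold", "must be >= 0")
  structure(list(k = as.integer(k),
                 deviation_threshold = deviation_threshold,
                 sustain = as.integer(sustain),
                 sd_floor = sd_floor,
                 mid_swing_fraction = mid_swing_fraction,
                 post_window = as.integer(post_window)),
            class = "reaction_config")
}
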