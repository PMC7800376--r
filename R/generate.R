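# Synthetic running-wheel sessions with planted ground truth.
#
# Coordinate conventions: x increases in the direction of locomotion, z is
# height above the wheel surface, y is lateral; all positions mm, frames
# 0-indexed externally via the `frame` column (internally 1-based vectors).
# The camera (head-fixed) frame keeps the nose stationary; world coordinates
# add the wheel displacement so that stance paws and engaged obstacles are
# stationary.

PAW_IDS <- c("LF", "RF", "LH", "RH")
LANDMARK_IDS <- c(PAW_IDS, "tail_base", "tail_mid", "nose", "obstacle")
PAW_PHASE <- c(LF = 0, RF = 0.5, LH = 0.5, RH = 0)
PAW_LATERAL <- c(LF = -8, RF = 8, LH = -10, RH = 10)

# smooth re-plan profile: unit displacement with an immediate velocity change
# at onset and zero terminal velocity (S(0)=0, S(1)=1, S'(1)=0)
mod_profile <- function(w) w * (2 - w)

# `speed_sd` is the SD of per-step (touchdown-to-touchdown) wheel speeds, the
# quantity entering the step-length law. The stride-level AR process is run
# slightly wider to compensate for stride-to-step averaging of limbs whose
# cycles span stride boundaries and for finite-session sampling under
# autocorrelation.
stride_speed_sd <- function(config) config$speed_sd * 1.045

#' Simulate a tracking session with obstacle trials and planted decisions
#'
#' Generates a full session of trot locomotion on a running wheel: stride-level
#' AR(1) wheel speeds, per-paw touchdown schedules with diagonal limb pairs in
#' phase, cosine swing profiles with half-sine height, obstacle trials with
#' uniformly jittered geometry, whisker-contact events a fixed reach anterior
#' of the nose, and -- on every trial with exactly one forepaw in swing at
#' contact -- a planted shorten/lengthen decision executed
#' `planted_latency` ms after contact. When contact falls so late in the swing
#' that the paw lands before the modification onset, the modification is
#' executed as a rapid corrective re-step from the unmodified landing; the
#' first frame at which the trajectory departs from its unmodified
#' continuation is always `contact + planted_latency` frames.
#'
#' Tracking confidences are identically 1; use [inject_tracking_artifacts()]
#' to add realistic tracking noise.
#'
#' @param config A [gait_config()].
#' @param seed Integer seed. Trial-level randomness uses fixed per-trial
#'   substreams, so trial `k` is reproducible independently of `n_trials`.
#' @return A list with components `session` (class `obs_session`: long-format
#'   two-view landmark table, wheel displacement trace, trial metadata) and
#'   `truth` (class `obs_truth`: per-trial ground truth, the per-paw step
#'   schedule, and the frame-by-frame stance matrix).
#' @export
generate_session <- function(config = gait_config(), seed = 1L) {
  validate_gait_config(config)
  fr <- config$frame_rate
  dt <- 1 / fr
  latfrm <- as.integer(round(config$planted_latency / 1000 * fr))
  duty <- config$duty_factor
  a <- config$step_length_intercept
  b <- config$step_length_slope
  mu <- config$mean_speed
  nt <- as.integer(config$n_trials)
  n_eng <- length(config$engage_distances)
  s_noise <- config$landing_noise_sd / sqrt(2)
  tau_eff <- config$decision_temperature
  if (!config$whiskers_present) {
    s_noise <- s_noise * config$whiskerless_noise_factor
    tau_eff <- tau_eff * config$whiskerless_temperature_factor
  }

  ## ---- per-trial random draws (substreams: trial k invariant to n_trials) --
  tdraw <- lapply(seq_len(nt), function(k) {
    with_seed(substream_seed(seed, 1000L + k), {
      list(e_jit = stats::runif(1, -config$engage_jitter, config$engage_jitter),
           s_jit = stats::runif(1, -config$obstacle_start_jitter,
                                config$obstacle_start_jitter),
           height = stats::runif(1, config$obstacle_height_range[1],
                                 config$obstacle_height_range[2]),
           light = stats::runif(1) < config$light_on_probability,
           eta = stats::rnorm(1, 0, config$contact_noise_sd),
           u_dec = stats::runif(1),
           delta = stats::runif(1, config$modification_delta[1],
                                config$modification_delta[2]),
           front_gap = stats::runif(1, 3, 8),
           clear_noise = stats::rnorm(4, 0, config$clearance_sd))
    })
  })
  lap <- (seq_len(nt) - 1L) %/% n_eng
  slot <- (seq_len(nt) - 1L) %% n_eng + 1L
  engage_pos <- (lap * config$reward_distance + config$engage_distances[slot] +
                   vapply(tdraw, `[[`, numeric(1), "e_jit")) * 1000
  total_mm <- max(engage_pos) +
    (config$obstacle_start_distance + config$obstacle_start_jitter) * 1000 + 500

  ## ---- stride-level speed process and schedule --------------------------
  rho <- config$speed_ar
  min_step <- max(5, a + b * max(0.15, mu - 4 * config$speed_sd))
  N <- as.integer(ceiling(total_mm / min_step) + 30)
  repeat {
    innov <- with_seed(substream_seed(seed, 11L),
                       stats::rnorm(N, 0, 1)) * stride_speed_sd(config) * sqrt(1 - rho^2)
    innov[1] <- innov[1] / sqrt(1 - rho^2)
    v_str <- mu + as.numeric(stats::filter(innov, rho, method = "recursive"))
    v_str <- pmax(v_str, 0.15)
    L0 <- a + b * v_str
    nfr <- pmax(6L, as.integer(round(L0 / (1000 * v_str) / dt)))
    dist_str <- cumsum(v_str * nfr * dt * 1000)
    if (dist_str[N] >= total_mm) break
    N <- as.integer(N * 1.5)
  }
  K <- which(dist_str >= total_mm)[1] + 3L
  v_str <- v_str[seq_len(K)]
  nfr <- nfr[seq_len(K)]
  sb <- cumsum(c(1L, nfr))            # stride k spans frames sb[k]..sb[k+1]-1
  v_frame <- rep(v_str, nfr)
  n_frames_raw <- length(v_frame)
  disp <- c(0, cumsum(v_frame * dt * 1000))[seq_len(n_frames_raw)]

  delta_mat <- with_seed(substream_seed(seed, 12L),
                         matrix(stats::rnorm(4 * (K + 2)), ncol = 4,
                                byrow = TRUE)) * s_noise
  ## fractional apex noise; the apex itself scales with step length x swing
  ## duration (higher, longer swings at speed), which keeps swing phase
  ## linearly decodable from the vertical paw velocity
  peak_eps <- with_seed(substream_seed(seed, 13L),
                        matrix(stats::rnorm(4 * (K + 2)), ncol = 4,
                               byrow = TRUE)) *
    (config$swing_peak_sd / config$swing_peak_height)
  colnames(delta_mat) <- colnames(peak_eps) <- PAW_IDS
  L_ref <- a + b * mu
  apex_ref <- L_ref * (1 - duty) * L_ref / (1000 * mu)

  home <- c(LF = config$paw_home_fore, RF = config$paw_home_fore,
            LH = config$paw_home_hind, RH = config$paw_home_hind)

  td <- X <- pk <- list()
  for (p in PAW_IDS) {
    tdp <- sb[seq_len(K)] + as.integer(round(PAW_PHASE[[p]] * nfr))
    if (tdp[1] > 1L) tdp <- c(1L, tdp)
    tdp <- tdp[tdp <= n_frames_raw]
    td[[p]] <- tdp
    X[[p]] <- disp[tdp] + home[[p]] + delta_mat[seq_along(tdp), p]
    n_p <- length(tdp)
    L_cyc <- c(diff(X[[p]]), L_ref)
    len_cyc <- c(diff(tdp), round(L_ref / (1000 * mu) / dt))
    tsw_cyc <- (len_cyc - round(duty * len_cyc)) * dt
    pk[[p]] <- pmax(config$swing_peak_height * (L_cyc * tsw_cyc) / apex_ref *
                      (1 + peak_eps[seq_len(n_p), p]), 3)
  }
  n_frames <- min(vapply(td, function(t) t[length(t)], integer(1))) - 1L
  v_frame <- v_frame[seq_len(n_frames)]
  disp <- disp[seq_len(n_frames)]
  fidx <- seq_len(n_frames)

  ## ---- base per-frame paw trajectories ----------------------------------
  xw <- zz <- matrix(0, n_frames, 4, dimnames = list(NULL, PAW_IDS))
  stance <- matrix(TRUE, n_frames, 4, dimnames = list(NULL, PAW_IDS))
  cyc_of <- list()
  for (p in PAW_IDS) {
    tdp <- td[[p]]
    cyc <- findInterval(fidx, tdp)
    cyc_of[[p]] <- cyc
    len <- tdp[cyc + 1L] - tdp[cyc]
    nst <- round(duty * len)
    j <- fidx - tdp[cyc]
    sw <- j >= nst
    u <- (j - nst + 0.5) / (len - nst)
    Xp <- X[[p]]
    xp <- Xp[cyc]
    xp[sw] <- Xp[cyc][sw] + (Xp[cyc + 1L][sw] - Xp[cyc][sw]) * (1 - cospi(u[sw])) / 2
    zp <- numeric(n_frames)
    zp[sw] <- pk[[p]][cyc][sw] * sinpi(u[sw])
    xw[, p] <- xp
    zz[, p] <- zp
    stance[, p] <- !sw
  }

  ## base step schedule (one row per cycle)
  steps_truth <- do.call(rbind, lapply(PAW_IDS, function(p) {
    tdp <- td[[p]]
    K_p <- length(tdp) - 1L
    len <- diff(tdp)
    nst <- round(duty * len)
    data.frame(paw = p, cycle = seq_len(K_p),
               td_frame = tdp[seq_len(K_p)],
               lo_frame = tdp[seq_len(K_p)] + as.integer(nst),
               land_frame = tdp[seq_len(K_p) + 1L],
               td_x = X[[p]][seq_len(K_p)],
               land_x = X[[p]][seq_len(K_p) + 1L],
               modified = FALSE)
  }))
  ## drop the warm-up first cycle (partial stride for the phase-offset limbs)
  ## and cycles extending past the session
  steps_truth <- steps_truth[steps_truth$land_frame <= n_frames &
                               steps_truth$cycle > 1L, ]
  steps_truth$length <- steps_truth$land_x - steps_truth$td_x

  ## ---- obstacle trials ---------------------------------------------------
  obst_x_world <- disp + config$nose_offset + config$obstacle_start_distance * 1000
  obst_z <- rep(mean(config$obstacle_height_range), n_frames)

  trial_rows <- vector("list", nt)
  for (k in seq_len(nt)) {
    dr <- tdraw[[k]]
    f_e <- findInterval(engage_pos[k], disp) + 1L
    if (f_e >= n_frames - 50L) next
    ow <- disp[f_e] + config$nose_offset +
      (config$obstacle_start_distance + dr$s_jit) * 1000
    w_end <- min(n_frames, findInterval(ow - config$nose_offset + 120, disp) + 1L)
    win <- f_e:w_end
    thresh <- ow - config$whisker_reach -
      (config$contact_speed_slope * (v_frame[win] - mu) + dr$eta)
    hit <- which(disp[win] + config$nose_offset >= thresh)
    if (length(hit) == 0L) next
    contact <- win[hit[1]]
    t_end <- min(n_frames, findInterval(ow - config$nose_offset + 100, disp) + 1L)
    obst_x_world[f_e:t_end] <- ow
    obst_z[f_e:t_end] <- dr$height

    ## forepaw in swing at contact
    insw <- !stance[contact, c("LF", "RF")]
    swing_paw <- NA_character_
    exclusion <- NA_character_
    label <- "unmodified"
    dpred <- NA_real_
    onset <- NA_integer_
    corrective <- NA
    new_land <- NA_real_
    if (sum(insw) == 1L) {
      swing_paw <- c("LF", "RF")[insw]
      tdp <- td[[swing_paw]]
      cyc <- cyc_of[[swing_paw]][contact]
      td_orig <- tdp[cyc + 1L]
      v_c <- v_frame[contact]
      dpred <- X[[swing_paw]][cyc] + a + b * v_c - ow
      p_len <- logistic((dpred - config$decision_threshold -
                           config$decision_height_coefficient * dr$height) / tau_eff)
      label <- if (dr$u_dec < p_len) "lengthened" else "shortened"
      pred_land_w <- dpred + ow
      new_land <- if (label == "lengthened") {
        max(pred_land_w, ow) + dr$delta
      } else {
        min(pred_land_w - dr$delta, ow - dr$front_gap)
      }
      onset <- contact + latfrm
      corrective <- onset >= td_orig
      if (cyc + 2L > length(tdp)) next
      ## limits of the re-planned segment
      lo_next <- tdp[cyc + 1L] + as.integer(round(duty * (tdp[cyc + 2L] - tdp[cyc + 1L])))
      base_x <- xw[onset - 1L, swing_paw]
      if (corrective) base_x <- X[[swing_paw]][cyc + 1L]
      new_land <- max(new_land, base_x - 25)     # bounded retraction
      Dx <- new_land - base_x
      R <- max(3L, ceiling(sqrt(abs(Dx) / 1.2)), ceiling(abs(Dx) / 6))
      ## keep >= 3 stance frames before the next lift-off so the landing
      ## survives the 20 ms stance debounce
      if (onset + R > lo_next - 3L) R <- lo_next - 3L - onset
      if (R >= 2L && onset < n_frames - R) {
        new_td <- onset + R
        i <- seq_len(R)
        w <- i / R
        S <- mod_profile(w)
        z_base <- zz[onset - 1L, swing_paw]
        A <- if (label == "lengthened") max(8, dr$height + config$clearance_margin) else
          if (corrective) 6 else 2
        xw[onset - 1L + i, swing_paw] <- base_x + Dx * S
        zz[onset - 1L + i, swing_paw] <- z_base * (1 - S) + A * sinpi(w)
        stance[onset - 1L + i, swing_paw] <- FALSE
        ## stance at the modified landing until the next scheduled lift-off
        if (new_td <= lo_next - 1L) {
          xw[new_td:(lo_next - 1L), swing_paw] <- new_land
          zz[new_td:(lo_next - 1L), swing_paw] <- 0
          stance[new_td:(lo_next - 1L), swing_paw] <- TRUE
        }
        ## rebuild the following swing from the modified landing
        td2 <- tdp[cyc + 2L]
        if (td2 > lo_next && lo_next <= n_frames && td2 <= n_frames + 1L) {
          jj <- lo_next:min(td2 - 1L, n_frames)
          u2 <- (jj - lo_next + 0.5) / (td2 - lo_next)
          X2 <- X[[swing_paw]][cyc + 2L]
          xw[jj, swing_paw] <- new_land + (X2 - new_land) * (1 - cospi(u2)) / 2
          stance[jj, swing_paw] <- FALSE
          zz[jj, swing_paw] <- pk[[swing_paw]][cyc + 1L] * sinpi(u2)
        }
        ## truth step schedule: this cycle now lands at new_land/new_td
        ri <- which(steps_truth$paw == swing_paw & steps_truth$cycle == cyc)
        steps_truth$land_frame[ri] <- new_td
        steps_truth$land_x[ri] <- new_land
        steps_truth$length[ri] <- new_land - steps_truth$td_x[ri]
        steps_truth$modified[ri] <- TRUE
        ri2 <- which(steps_truth$paw == swing_paw & steps_truth$cycle == cyc + 1L)
        if (length(ri2)) {
          steps_truth$td_frame[ri2] <- new_td
          steps_truth$td_x[ri2] <- new_land
          steps_truth$length[ri2] <- steps_truth$land_x[ri2] - new_land
          steps_truth$modified[ri2] <- TRUE   # recovery step off the gait law
        }
      } else {
        label <- "unmodified"
        onset <- NA_integer_
        corrective <- NA
        new_land <- NA_real_
      }
    } else {
      exclusion <- if (all(insw)) "both_swing" else "both_stance"
    }

    trial_rows[[k]] <- data.frame(
      trial = k, engage_frame = f_e, engage_position_m = engage_pos[k] / 1000,
      obstacle_height = dr$height, light = dr$light,
      obstacle_x_world = ow, contact_frame = contact,
      contact_pos_rel_nose = ow - (disp[contact] + config$nose_offset),
      v_contact = v_frame[contact],
      swing_paw = swing_paw, exclusion = exclusion, label = label,
      delta_pred_true = dpred, onset_frame = onset, corrective = corrective,
      modified_landing_x = new_land, trial_end_frame = t_end)
  }
  truth_trials <- do.call(rbind, trial_rows)

  ## ---- obstacle clearance bumps ------------------------------------------
  for (k in seq_len(if (is.null(truth_trials)) 0L else nrow(truth_trials))) {
    tr <- truth_trials[k, ]
    wstart <- tr$engage_frame
    wend <- tr$trial_end_frame
    for (pi in seq_along(PAW_IDS)) {
      p <- PAW_IDS[pi]
      seg <- wstart:wend
      beyond <- xw[seg, p] >= tr$obstacle_x_world
      if (!any(beyond) || all(beyond)) next
      fc <- seg[which(beyond)[1]]
      if (stance[fc, p]) next                       # crossing at touchdown
      run0 <- fc
      while (run0 > 1L && !stance[run0 - 1L, p]) run0 <- run0 - 1L
      run1 <- fc
      while (run1 < n_frames && !stance[run1 + 1L, p]) run1 <- run1 + 1L
      W <- max(3L, round(0.5 * (run1 - run0 + 1L)))
      target <- tr$obstacle_height + config$clearance_margin +
        tdraw[[tr$trial]]$clear_noise[pi]
      need <- target - zz[fc, p]
      if (need <= 0) next
      lo_clip <- max(run0, fc - W)
      ## the decision paw shows no obstacle-driven change before the planted
      ## reaction latency (a leaking bump would fake a pre-latency reaction)
      if (!is.na(tr$swing_paw) && identical(p, tr$swing_paw))
        lo_clip <- max(lo_clip, tr$contact_frame + latfrm)
      if (lo_clip > min(run1, fc + W)) next
      ff <- lo_clip:min(run1, fc + W)
      zz[ff, p] <- zz[ff, p] + need * cospi((ff - fc) / (2 * W))^2
    }
  }

  ## ---- body angle, tail height, assembly ---------------------------------
  ar_trace <- function(off, m, s, r = 0.98) {
    e <- with_seed(substream_seed(seed, off), stats::rnorm(n_frames)) *
      s * sqrt(1 - r^2)
    e[1] <- e[1] / sqrt(1 - r^2)
    m + as.numeric(stats::filter(e, r, method = "recursive"))
  }
  body_angle <- ar_trace(14L, 0, config$body_angle_sd)
  tail_h <- pmax(1, ar_trace(15L, config$tail_height_mean, config$tail_height_sd))

  frame0 <- fidx                    # frame index, 1-based throughout
  cam <- function(wx) wx - disp
  blocks <- list()
  add <- function(view, landmark, xcam, ycoord) {
    blocks[[length(blocks) + 1L]] <<- data.frame(
      frame = frame0, view = view, landmark = landmark,
      x = xcam, y = ycoord, confidence = 1)
  }
  for (p in PAW_IDS) {
    add("top", p, cam(xw[, p]), zz[, p])
    add("bottom", p, cam(xw[, p]), rep(PAW_LATERAL[[p]], n_frames))
  }
  tb_y <- -60 * sinpi(body_angle / 180)
  add("top", "tail_base", rep(-30, n_frames), tail_h)
  add("bottom", "tail_base", rep(-30, n_frames), tb_y)
  add("top", "tail_mid", rep(-60, n_frames), tail_h + 1)
  add("bottom", "tail_mid", rep(-60, n_frames), tb_y / 2)
  add("top", "nose", rep(config$nose_offset, n_frames), rep(12, n_frames))
  add("bottom", "nose", rep(config$nose_offset, n_frames), rep(0, n_frames))
  add("top", "obstacle", cam(obst_x_world), obst_z)
  add("bottom", "obstacle", cam(obst_x_world), rep(0, n_frames))
  tracking <- do.call(rbind, blocks)

  meta <- if (is.null(truth_trials)) NULL else data.frame(
    trial = truth_trials$trial,
    obstacle_height_mm = truth_trials$obstacle_height,
    engage_position_m = truth_trials$engage_position_m,
    light = truth_trials$light,
    condition = if (config$whiskers_present) "whiskers" else "no_whiskers",
    engage_frame = truth_trials$engage_frame)

  session <- structure(list(tracking = tracking,
                            wheel = disp,
                            trials = meta,
                            frame_rate = fr,
                            n_frames = n_frames),
                       class = "obs_session")
  truth <- structure(list(trials = truth_trials,
                          steps = steps_truth,
                          stance = stance,
                          paw_x_world = xw,
                          paw_z = zz,
                          wheel_velocity = v_frame,
                          params = list(a = a, b = b,
                                        sigma = config$landing_noise_sd,
                                        placement_sd = s_noise,
                                        tau_eff = tau_eff,
                                        latency_frames = latfrm),
                          config = config,
                          seed = seed),
                     class = "obs_truth")
  list(session = session, truth = truth)
}

#' @export
print.obs_session <- function(x, ...) {
  cat(sprintf("<obs_session> %d frames @ %g Hz, %d landmarks x 2 views, %d trials\n",
              x$n_frames, x$frame_rate, length(unique(x$tracking$landmark)),
              if (is.null(x$trials)) 0L else nrow(x$trials)))
  invisible(x)
}

#' @export
print.obs_truth <- function(x, ...) {
  tab <- table(x$trials$label)
  cat("<obs_truth>", nrow(x$trials), "trials:",
      paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' Sample the trial context distribution of the planted decision rule
#'
#' Draws independent whisker-contact contexts (running speed, swing phase,
#' obstacle geometry, placement noise) from the same distributions the session
#' generator uses, and returns the implied predicted landing distance for the
#' forepaw in swing at contact. Used by [calibrate_decision_temperature()] and
#' for fast parameter-recovery experiments that do not need full sessions.
#'
#' @param n Number of contexts.
#' @param config A [gait_config()].
#' @param seed Integer seed.
#' @return A data frame with columns `delta_pred` (mm, relative to the
#'   obstacle; negative = in front), `height` (mm), `speed` (m/s), and
#'   `swing_frac` (phase of contact within the swing, 0-1).
#' @export
sample_decision_contexts <- function(n, config = gait_config(), seed = 1L) {
  validate_gait_config(config)
  dt <- 1 / config$frame_rate
  a <- config$step_length_intercept
  b <- config$step_length_slope
  mu <- config$mean_speed
  s_noise <- config$landing_noise_sd / sqrt(2)
  if (!config$whiskers_present) s_noise <- s_noise * config$whiskerless_noise_factor
  with_seed(seed, {
    v <- pmax(stats::rnorm(n, mu, stride_speed_sd(config)), 0.15)
    nfr <- pmax(6, round((a + b * v) / (1000 * v) / dt))
    nst <- round(config$duty_factor * nfr)
    nsw <- nfr - nst
    j <- floor(stats::runif(n) * nsw)
    delta <- stats::rnorm(n, 0, s_noise)
    eta <- stats::rnorm(n, 0, config$contact_noise_sd)
    overshoot <- stats::runif(n, 0, v * dt * 1000)
    h <- stats::runif(n, config$obstacle_height_range[1],
                      config$obstacle_height_range[2])
    dpred <- config$paw_home_fore + delta + a + b * v -
      v * 1000 * dt * (nst + j) -
      config$nose_offset - config$whisker_reach -
      (config$contact_speed_slope * (v - mu) + eta) + overshoot
    data.frame(delta_pred = dpred, height = h, speed = v,
               swing_frac = (j + 0.5) / nsw)
  })
}

#' Planted shorten/lengthen decision rule
#'
#' The probability of lengthening is
#' `plogis((delta_pred - theta - c * height) / tau)`: steps predicted to land
#' at or beyond the (height-shifted) threshold are lengthened to clear the
#' obstacle in one step, steps predicted to land well in front are shortened.
#'
#' @param predicted_landing Predicted landing distance(s) in mm relative to
#'   the obstacle (negative = in front).
#' @param obstacle_height Obstacle height(s), mm.
#' @param config A [gait_config()]; supplies the threshold, height
#'   coefficient and temperature (degraded when `whiskers_present = FALSE`).
#' @param u Optional uniform draws (for reproducibility); defaults to
#'   `runif()` on the current RNG stream.
#' @return Character vector of labels, `"shortened"` or `"lengthened"`.
#' @export
plant_decision <- function(predicted_landing, obstacle_height, config, u = NULL) {
  tau <- config$decision_temperature
  if (!is_scalar_num(tau) || tau <= 0)
    stop_config("decision_temperature", "must be > 0")
  if (!config$whiskers_present) tau <- tau * config$whiskerless_temperature_factor
  p_len <- logistic((predicted_landing - config$decision_threshold -
                       config$decision_height_coefficient * obstacle_height) / tau)
  if (is.null(u)) u <- stats::runif(length(p_len))
  ifelse(u < p_len, "lengthened", "shortened")
}

#' Calibrate the decision temperature to a target Bayes accuracy
#'
#' Finds, by bisection, the logit scale `tau` at which the planted decision
#' rule's Bayes accuracy `E[max(p, 1 - p)]` over the generator's trial-context
#' distribution equals `target_accuracy`. The default target of 0.73 makes the
#' best achievable decision-model accuracy on synthetic cohorts match the
#' accuracy reported for real mice.
#'
#' @param config A [gait_config()].
#' @param target_accuracy Desired Bayes accuracy, in (0.5, 1).
#' @param n Monte-Carlo sample size.
#' @param seed Seed for the context sample.
#' @param tau_range Search interval for `tau` (mm).
#' @return The calibrated temperature (numeric scalar) with attribute
#'   `"accuracy"` giving the achieved Monte-Carlo accuracy.
#' @export
calibrate_decision_temperature <- function(config = gait_config(),
                                           target_accuracy = 0.73,
                                           n = 2e5, seed = 1L,
                                           tau_range = c(0.05, 500)) {
  if (!is_scalar_num(target_accuracy) || target_accuracy <= 0.5 ||
      target_accuracy >= 1)
    stop_config("target_accuracy", "must lie in (0.5, 1)")
  ctx <- sample_decision_contexts(n, config, seed)
  margin <- abs(ctx$delta_pred - config$decision_threshold -
                  config$decision_height_coefficient * ctx$height)
  acc <- function(tau) mean(logistic(margin / tau))
  lo <- tau_range[1]; hi <- tau_range[2]
  a_hi <- acc(hi); a_lo <- acc(lo)
  if (a_hi >= target_accuracy) {
    warning(sprintf(
      "target accuracy %.3f not reachable below tau = %g (accuracy there %.3f); returning the upper bound",
      target_accuracy, hi, a_hi))
    tau <- hi
    attr(tau, "accuracy") <- a_hi
    return(tau)
  }
  if (a_lo < target_accuracy) {
    stop(sprintf(
      "calibration error: target accuracy %.3f outside achievable range [%.3f, %.3f] on this feature distribution",
      target_accuracy, a_hi, a_lo))
  }
  for (it in seq_len(200)) {
    mid <- sqrt(lo * hi)
    a_mid <- acc(mid)
    if (abs(a_mid - target_accuracy) < 5e-4 || (hi / lo) < 1.0005) break
    if (a_mid > target_accuracy) lo <- mid else hi <- mid
  }
  tau <- mid
  attr(tau, "accuracy") <- a_mid
  tau
}
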