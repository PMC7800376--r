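# Reaction-time estimation: kNN-matched control-step families, deviation
# traces, onset detection, control validation, and time-to-contact.

#' Extract a swing-aligned step trajectory
#'
#' Returns the (x, z) trajectory of a paw over `width` frames starting at its
#' lift-off frame, with x relative to the lift-off (stance) position. Frames
#' at or beyond `bound` (typically the next lift-off of the same paw) are NA.
#'
#' @param kin World-frame `obs_kinematics`.
#' @param paw Paw name.
#' @param lift_off Lift-off frame of the step.
#' @param width Window length in frames.
#' @param bound First frame that no longer belongs to this step cycle.
#' @return `width x 2` matrix (columns x, z), NA-padded.
#' @export
step_trajectory <- function(kin, paw, lift_off, width, bound = Inf) {
  fr <- lift_off:(lift_off + width - 1L)
  ok <- fr <= min(bound - 1L, kin$n_frames)
  out <- matrix(NA_real_, width, 2, dimnames = list(NULL, c("x", "z")))
  out[ok, "x"] <- kin$positions[fr[ok], "x", paw] -
    kin$positions[lift_off - 1L, "x", paw]
  out[ok, "z"] <- kin$positions[fr[ok], "z", paw]
  out
}

#' k-nearest-neighbour matched control steps
#'
#' Selects, from a pool of control steps, the `k` steps whose swing-aligned
#' pre-contact (x, z) trajectories are closest (Euclidean distance) to the
#' query trajectory. Averaging the family estimates what the paw would have
#' done had no obstacle been presented.
#'
#' @param query `m x 2` matrix: the trial's trajectory from swing onset to
#'   whisker contact.
#' @param pool List of trajectory matrices (>= m rows each), as from
#'   [step_trajectory()].
#' @param k Family size.
#' @return Integer indices into `pool` (best first), with attribute
#'   `"distance"`.
#' @export
match_control_steps <- function(query, pool, k = 40) {
  if (length(pool) < k)
    stop(sprintf("control-step pool too small: %d < k = %d", length(pool), k))
  m <- nrow(query)
  q <- as.numeric(query)
  d <- vapply(pool, function(p) {
    dd <- as.numeric(p[seq_len(m), , drop = FALSE]) - q
    sqrt(sum(dd^2))
  }, numeric(1))
  ord <- order(d)[seq_len(k)]
  structure(ord, distance = d[ord])
}

#' Deviation of a trial trajectory from its matched control family
#'
#' Per-frame difference between the actual trajectory and the family mean,
#' with the family's per-frame SD envelope, and a combined normalised
#' deviation magnitude (root-mean-square of the per-coordinate z-scores, so a
#' constant 1-SD offset in every coordinate gives a normalised deviation of
#' 1). Frames covered by fewer than half the family are dropped (flagged).
#'
#' @param actual `W x 2` trajectory matrix of the trial.
#' @param family List of `W x 2` matrices (the matched control steps).
#' @param contact_index Row of `actual` corresponding to whisker contact.
#' @param sd_floor Lower bound on the per-frame family SD (mm).
#' @return Object of class `deviation_trace`: list with `deviation` (W x 2),
#'   `family_sd`, `family_mean`, `norm` (combined normalised deviation),
#'   `coverage`, `contact_index`, `truncated`.
#' @export
deviation_trace <- function(actual, family, contact_index, sd_floor = 0.1) {
  W <- nrow(actual)
  k <- length(family)
  arr <- array(unlist(family), c(W, 2, k))
  coverage <- apply(!is.na(arr[, 1, , drop = FALSE]), 1, sum)
  fmean <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  fsd <- apply(arr, c(1, 2), stats::sd, na.rm = TRUE)
  valid <- coverage >= k / 2 & !is.na(actual[, 1])
  dev <- actual - fmean
  dev[!valid, ] <- NA
  nsd <- pmax(fsd, sd_floor)
  zsc <- dev / nsd
  nrm <- sqrt(rowMeans(zsc^2))
  structure(list(deviation = dev, family_sd = fsd, family_mean = fmean,
                 norm = nrm, coverage = coverage,
                 contact_index = contact_index,
                 truncated = any(!valid[seq_len(min(which(valid), W))])),
            class = "deviation_trace")
}

#' Reaction-onset latency from a deviation trace
#'
#' The latency is the time from whisker contact to the first frame at which
#' the normalised deviation exceeds the threshold (2.5 family SDs by default)
#' and stays above it for `sustain` consecutive frames.
#'
#' @param trace A [deviation_trace()].
#' @param cfg A [reaction_config()].
#' @param frame_rate Hz.
#' @return Latency in ms, or `NA` if the threshold is never crossed.
#' @export
onset_latency <- function(trace, cfg = reaction_config(), frame_rate = 250) {
  ci <- trace$contact_index
  nrm <- trace$norm
  W <- length(nrm)
  if (ci > W) return(NA_real_)
  above <- !is.na(nrm) & nrm > cfg$deviation_threshold
  for (f in ci:W) {
    run <- f:min(W, f + cfg$sustain - 1L)
    if (length(run) == cfg$sustain && all(above[run]))
      return((f - ci) / frame_rate * 1000)
  }
  NA_real_
}

## shared machinery: control-step pool for a paw, outside trial windows
control_pool_steps <- function(steps, paw, exclude_windows) {
  s <- steps[steps$paw == paw & !steps$is_over_obstacle, ]
  if (nrow(s) == 0) return(s)
  keep <- rep(TRUE, nrow(s))
  for (w in exclude_windows) {
    keep <- keep & (s$touch_down_frame < w[1] | s$lift_off_frame > w[2])
  }
  s[keep & s$lift_off_frame > 1, ]
}

#' Per-trial reaction latencies for a session
#'
#' Runs the full matched-control reaction analysis: for every trial whose
#' swing paw was mid-swing at whisker contact, matches a family of `k`
#' control steps to the pre-contact trajectory, computes the deviation trace,
#' and estimates the onset latency.
#'
#' @param kin World-frame `obs_kinematics`.
#' @param steps A `step_table`.
#' @param trials Data frame with `trial`, `contact_frame`, and optionally
#'   `swing_paw` (otherwise determined from the step table).
#' @param cfg A [reaction_config()].
#' @return Object of class `reaction_estimate`: per-trial data frame
#'   (`trial`, `paw`, `eligible`, `latency_ms`) plus `median_latency_ms` and
#'   the fraction of eligible trials with a detected onset.
#' @export
reaction_latencies <- function(kin, steps, trials, cfg = reaction_config()) {
  stopifnot(kin$frame_tag == "world")
  fr <- kin$frame_rate
  windows <- lapply(seq_len(nrow(trials)), function(i) {
    cf <- trials$contact_frame[i]
    c(cf - 400L, cf + 200L)
  })
  pools <- list()
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    cf <- trials$contact_frame[i]
    out <- data.frame(trial = trials$trial[i], paw = NA_character_,
                      eligible = FALSE, latency_ms = NA_real_)
    if (is.na(cf)) return(out)
    pw <- if (!is.null(trials$swing_paw)) trials$swing_paw[i] else
      paw_in_swing_at_contact(steps, cf)
    if (is.na(pw) || pw %in% c("BOTH_SWING", "BOTH_STANCE")) return(out)
    out$paw <- pw
    s <- steps[steps$paw == pw & steps$lift_off_frame <= cf &
                 cf < steps$touch_down_frame, ]
    if (nrow(s) != 1L) return(out)
    if (is.null(pools[[pw]])) {
      ps <- control_pool_steps(steps, pw, windows)
      W <- max(cf - s$lift_off_frame + 1L + cfg$post_window, 24L)
      pools[[pw]] <<- list(steps = ps, median_swing = stats::median(
        ps$touch_down_frame - ps$lift_off_frame))
    }
    ps <- pools[[pw]]$steps
    msw <- pools[[pw]]$median_swing
    ## mid-swing restriction, judged against the typical swing duration
    phase <- (cf - s$lift_off_frame) / msw
    lo_ph <- (1 - cfg$mid_swing_fraction) / 2
    if (is.na(phase) || phase < lo_ph || phase > 1 - lo_ph) return(out)
    out$eligible <- TRUE
    m <- cf - s$lift_off_frame + 1L
    W <- m + cfg$post_window
    query <- step_trajectory(kin, pw, s$lift_off_frame, W)
    if (nrow(ps) < cfg$k) return(out)
    ptr <- lapply(seq_len(nrow(ps)), function(j) {
      nxt <- ps$touch_down_frame[j] +
        (ps$touch_down_frame[j] - ps$cycle_start_frame[j])  # conservative bound
      step_trajectory(kin, pw, ps$lift_off_frame[j], W, bound = nxt)
    })
    idx <- match_control_steps(query[seq_len(m), , drop = FALSE], ptr, cfg$k)
    trace <- deviation_trace(query, ptr[idx], contact_index = m,
                             sd_floor = cfg$sd_floor)
    out$latency_ms <- onset_latency(trace, cfg, fr)
    out
  })
  res <- do.call(rbind, rows)
  structure(list(trials = res,
                 median_latency_ms = stats::median(res$latency_ms, na.rm = TRUE),
                 n_eligible = sum(res$eligible),
                 detection_rate = mean(!is.na(res$latency_ms[res$eligible]))),
            class = "reaction_estimate")
}

#' @export
print.reaction_estimate <- function(x, ...) {
  cat(sprintf("<reaction_estimate> %d eligible trials, median latency %.1f ms (onset detected on %.0f%%)\n",
              x$n_eligible, x$median_latency_ms, 100 * x$detection_rate))
  invisible(x)
}

#' Control validation of the reaction pipeline
#'
#' Re-runs the matched-family analysis on control steps only, using earlier
#' steps to predict the penultimate pre-contact step. With an unbiased
#' pipeline the deviations are centred on zero and onsets are rarely
#' (falsely) detected.
#'
#' @param kin World-frame `obs_kinematics`.
#' @param steps A `step_table`.
#' @param trials Data frame with `trial`, `contact_frame`, `swing_paw`.
#' @param cfg A [reaction_config()].
#' @return List with `n`, `mean_norm_dev` (mean normalised deviation over the
#'   post-window), `mean_dev_mm` (signed mean deviation, x and z) and
#'   `false_onset_rate`.
#' @export
control_validation <- function(kin, steps, trials, cfg = reaction_config()) {
  fr <- kin$frame_rate
  windows <- lapply(seq_len(nrow(trials)), function(i) {
    c(trials$contact_frame[i] - 400L, trials$contact_frame[i] + 200L)
  })
  norms <- c(); devx <- c(); devz <- c(); onsets <- c()
  for (i in seq_len(nrow(trials))) {
    cf <- trials$contact_frame[i]
    pw <- trials$swing_paw[i]
    if (is.na(cf) || is.na(pw) || pw %in% c("BOTH_SWING", "BOTH_STANCE")) next
    ctrl <- suppressWarnings(control_steps(steps, cf, pw))
    if (nrow(ctrl) < 2L) next
    pen <- ctrl[1, ]                       # penultimate (latest) control step
    pool <- control_pool_steps(steps, pw, windows)
    pool <- pool[pool$touch_down_frame < pen$lift_off_frame |
                   pool$lift_off_frame > pen$touch_down_frame, ]
    if (nrow(pool) < cfg$k) next
    sw_len <- pen$touch_down_frame - pen$lift_off_frame
    m <- max(2L, round(sw_len / 2))        # pseudo-contact at mid-swing
    W <- m + cfg$post_window
    query <- step_trajectory(kin, pw, pen$lift_off_frame, W)
    ptr <- lapply(seq_len(nrow(pool)), function(j) {
      nxt <- pool$touch_down_frame[j] +
        (pool$touch_down_frame[j] - pool$cycle_start_frame[j])
      step_trajectory(kin, pw, pool$lift_off_frame[j], W, bound = nxt)
    })
    idx <- match_control_steps(query[seq_len(m), , drop = FALSE], ptr, cfg$k)
    trace <- deviation_trace(query, ptr[idx], contact_index = m,
                             sd_floor = cfg$sd_floor)
    post <- m:min(W, length(trace$norm))
    norms <- c(norms, mean(trace$norm[post], na.rm = TRUE))
    devx <- c(devx, mean(trace$deviation[post, "x"], na.rm = TRUE))
    devz <- c(devz, mean(trace$deviation[post, "z"], na.rm = TRUE))
    onsets <- c(onsets, !is.na(onset_latency(trace, cfg, fr)))
  }
  list(n = length(norms),
       mean_norm_dev = mean(norms),
       mean_dev_mm = c(x = mean(devx), z = mean(devz)),
       false_onset_rate = if (length(onsets)) mean(onsets) else NA_real_)
}

#' Time to contact: when would a paw intercept the obstacle?
#'
#' Takes the most anterior x position across all paws in each frame, fits a
#' line to this signal over the 100 frames (400 ms) preceding whisker
#' contact, and extrapolates the time at which it would reach the obstacle if
#' no modifications were made.
#'
#' @param kin World-frame `obs_kinematics`.
#' @param contact_frame Whisker-contact frame.
#' @param obstacle_x Obstacle position (mm, world frame).
#' @param n_fit Number of pre-contact frames in the fit.
#' @return Time to contact in ms, or `NA` (flagged via attribute `"reason"`)
#'   when the paws are not approaching (slope <= 0) or the estimate is not
#'   finite.
#' @export
time_to_contact <- function(kin, contact_frame, obstacle_x, n_fit = 100) {
  paws <- intersect(c("LF", "RF", "LH", "RH"), dimnames(kin$positions)[[3]])
  if (contact_frame - n_fit < 1)
    stop(sprintf("need %d frames before contact", n_fit))
  fr <- (contact_frame - n_fit):(contact_frame - 1L)
  ant <- apply(kin$positions[fr, "x", paws], 1, max)
  tt <- (fr - contact_frame) / kin$frame_rate          # seconds, 0 at contact
  fit <- stats::lm(ant ~ tt)
  slope <- unname(stats::coef(fit)[2])                 # mm/s
  if (!is.finite(slope) || slope <= 0)
    return(structure(NA_real_, reason = "not approaching"))
  at_contact <- unname(stats::coef(fit)[1])
  ttc <- (obstacle_x - at_contact) / slope * 1000
  if (!is.finite(ttc) || ttc < 0)
    return(structure(NA_real_, reason = "behind obstacle"))
  ttc
}
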