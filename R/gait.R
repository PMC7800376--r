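# Stance detection, step segmentation, control steps, Hildebrand diagrams,
# trial success, and paw/obstacle height correlations.

#' Frame-wise stance detection with median debounce
#'
#' A paw is in stance when its world-frame horizontal speed is within the
#' velocity tolerance of zero -- equivalently, when its camera-frame speed is
#' within the tolerance of the wheel-surface speed -- and its height is within
#' the height tolerance of the wheel surface. The frame-wise call is then
#' debounced with a median filter (20 ms by default, 5 frames at 250 Hz).
#'
#' @param paw_z Height trace (mm above the wheel surface).
#' @param paw_vx_world World-frame horizontal paw velocity (m/s); see
#'   [landmark_velocity()] on un-head-fixed kinematics.
#' @param cfg A [stance_config()].
#' @param frame_rate Hz (sets the debounce window).
#' @return Logical stance trace.
#' @export
detect_stance <- function(paw_z, paw_vx_world, cfg = stance_config(),
                          frame_rate = 250) {
  if (length(paw_z) != length(paw_vx_world))
    stop("paw_z and paw_vx_world must have the same length")
  raw <- abs(paw_vx_world) <= cfg$velocity_tolerance &
    paw_z <= cfg$height_tolerance
  median_debounce(raw, debounce_frames(cfg, frame_rate))
}

#' @rdname detect_stance
#' @param paw_vx_camera Camera-frame (head-fixed) horizontal paw velocity
#'   (m/s). In the camera frame the wheel surface moves backwards at the wheel
#'   speed, so stance paws satisfy `paw_vx_camera = -wheel_velocity`.
#' @param wheel_vel Wheel velocity trace (m/s).
#' @export
detect_stance_camera <- function(paw_z, paw_vx_camera, wheel_vel,
                                 cfg = stance_config(), frame_rate = 250) {
  detect_stance(paw_z, paw_vx_camera + wheel_vel, cfg, frame_rate)
}

#' Segment a debounced stance trace into steps
#'
#' One step per maximal swing interval: the lift-off frame is the first swing
#' frame, the touch-down frame the first stance frame after it. The lift-off
#' position is the stance position immediately before lift-off, the landing
#' position the position at touch-down; step length is their difference. Peak
#' height is the swing maximum of z. Partial swings at the session edges are
#' discarded. Each step also records the mean wheel speed over its full cycle
#' (previous touch-down to touch-down), the window over which the step-length
#' versus speed law is defined.
#'
#' @param stance Logical stance trace (debounced).
#' @param x_world World-frame paw x trace (mm).
#' @param z Paw height trace (mm).
#' @param wheel_vel Wheel velocity trace (m/s), for per-step speeds.
#' @param paw Paw label stored in the output.
#' @param frame_rate Hz.
#' @return A `step_table` data frame (possibly 0 rows): one row per step with
#'   columns `paw`, `cycle_start_frame`, `lift_off_frame`, `touch_down_frame`,
#'   `lift_off_x`, `landing_x`, `length`, `peak_height`, `speed`,
#'   `duration_ms`, `is_control`, `is_over_obstacle`, `trial`.
#' @export
segment_steps <- function(stance, x_world, z, wheel_vel = NULL,
                          paw = NA_character_, frame_rate = 250) {
  stopifnot(length(stance) == length(x_world), length(z) == length(x_world))
  r <- rle(as.logical(stance))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  swings <- which(!r$values)
  ## interior swings only (bounded by stance on both sides)
  swings <- swings[swings > 1L & swings < length(r$values)]
  if (length(swings) == 0L) {
    return(empty_step_table())
  }
  lo <- starts[swings]
  tdn <- ends[swings] + 1L
  cyc0 <- starts[swings - 1L]          # preceding stance onset (cycle start)
  rows <- data.frame(
    paw = paw,
    cycle_start_frame = cyc0,
    lift_off_frame = lo,
    touch_down_frame = tdn,
    lift_off_x = x_world[lo - 1L],
    landing_x = x_world[tdn],
    peak_height = vapply(seq_along(lo),
                         function(i) max(z[lo[i]:(tdn[i] - 1L)]), numeric(1)),
    speed = if (is.null(wheel_vel)) NA_real_ else
      vapply(seq_along(lo),
             function(i) mean(wheel_vel[cyc0[i]:tdn[i]]), numeric(1)),
    duration_ms = (tdn - lo) / frame_rate * 1000,
    is_control = FALSE,
    is_over_obstacle = FALSE,
    trial = NA_integer_)
  rows$length <- rows$landing_x - rows$lift_off_x
  class(rows) <- c("step_table", "data.frame")
  rows
}

empty_step_table <- function() {
  out <- data.frame(paw = character(), cycle_start_frame = integer(),
                    lift_off_frame = integer(), touch_down_frame = integer(),
                    lift_off_x = numeric(), landing_x = numeric(),
                    peak_height = numeric(), speed = numeric(),
                    duration_ms = numeric(), is_control = logical(),
                    is_over_obstacle = logical(), trial = integer(),
                    length = numeric())
  class(out) <- c("step_table", "data.frame")
  out
}

#' Stance and step segmentation for all four paws of a session
#'
#' Convenience wrapper running [detect_stance()] and [segment_steps()] on
#' world-frame kinematics for LF, RF, LH and RH.
#'
#' @param kin An `obs_kinematics` in the world frame (see [unheadfix()]).
#' @param cfg A [stance_config()].
#' @return A `step_table` with all paws, plus attribute `"stance"` (logical
#'   frames-by-paw matrix).
#' @export
step_table <- function(kin, cfg = stance_config()) {
  stopifnot(inherits(kin, "obs_kinematics"))
  if (kin$frame_tag != "world")
    stop("step_table() expects world-frame kinematics; call unheadfix() first")
  paws <- intersect(c("LF", "RF", "LH", "RH"), dimnames(kin$positions)[[3]])
  stance_mat <- matrix(NA, kin$n_frames, length(paws),
                       dimnames = list(NULL, paws))
  tabs <- lapply(paws, function(p) {
    vx <- landmark_velocity(kin, p, "x")
    st <- detect_stance(kin$positions[, "z", p], vx, cfg, kin$frame_rate)
    stance_mat[, p] <<- st
    segment_steps(st, kin$positions[, "x", p], kin$positions[, "z", p],
                  kin$wheel_velocity, paw = p, frame_rate = kin$frame_rate)
  })
  out <- do.call(rbind, tabs)
  class(out) <- c("step_table", "data.frame")
  attr(out, "stance") <- stance_mat
  out
}

#' Control steps: the two latest steps completed before whisker contact
#'
#' @param steps A `step_table`.
#' @param contact_frame Whisker-contact frame of the trial.
#' @param paw Paw to select.
#' @return Up to two rows of `steps` (latest first) flagged `is_control`;
#'   attribute `"insufficient"` is `TRUE` with a warning when fewer than two
#'   exist.
#' @export
control_steps <- function(steps, contact_frame, paw) {
  cand <- steps[steps$paw == paw & steps$touch_down_frame < contact_frame, ]
  cand <- cand[order(cand$touch_down_frame, decreasing = TRUE), ]
  out <- utils::head(cand, 2L)
  if (nrow(out) > 0) out$is_control <- TRUE
  if (nrow(out) < 2L) {
    warning(sprintf("only %d control step(s) available for %s before frame %s",
                    nrow(out), paw, contact_frame))
    attr(out, "insufficient") <- TRUE
  }
  out
}

#' Which forepaw is in swing at whisker contact?
#'
#' Decision analyses focus on the forepaw in swing at whisker contact; trials
#' where both forepaws are in swing or both in stance are excluded.
#'
#' @param steps A `step_table` containing LF and RF steps.
#' @param contact_frame Whisker-contact frame.
#' @return `"LF"` or `"RF"`, or an exclusion code `"BOTH_SWING"` /
#'   `"BOTH_STANCE"`.
#' @export
paw_in_swing_at_contact <- function(steps, contact_frame) {
  insw <- vapply(c("LF", "RF"), function(p) {
    s <- steps[steps$paw == p, ]
    any(s$lift_off_frame <= contact_frame & contact_frame < s$touch_down_frame)
  }, logical(1))
  if (all(insw)) return("BOTH_SWING")
  if (!any(insw)) return("BOTH_STANCE")
  c("LF", "RF")[insw]
}

#' Trial success from paw-contact intervals
#'
#' A trial is successful when the total duration of paw contact with the
#' obstacle is at most `max_contact_ms` (20 ms); an individual paw is
#' successful when it never touches the obstacle. Overlapping intervals of one
#' paw are merged before summation.
#'
#' @param contacts Data frame with columns `paw`, `start_frame`, `end_frame`
#'   (inclusive frame ranges); zero rows mean no contact.
#' @param frame_rate Hz.
#' @param max_contact_ms Success threshold (inclusive).
#' @param paws Paws to report individually.
#' @return List with `success` (logical), `total_ms`, and `per_paw` (named
#'   logical vector) plus `per_paw_ms`.
#' @export
trial_success <- function(contacts, frame_rate = 250, max_contact_ms = 20,
                          paws = c("LF", "RF", "LH", "RH")) {
  per_ms <- stats::setNames(numeric(length(paws)), paws)
  if (!is.null(contacts) && nrow(contacts) > 0) {
    for (p in unique(contacts$paw)) {
      iv <- contacts[contacts$paw == p, c("start_frame", "end_frame")]
      iv <- iv[order(iv$start_frame), , drop = FALSE]
      merged <- list()
      cur <- c(iv$start_frame[1], iv$end_frame[1])
      for (i in seq_len(nrow(iv))[-1]) {
        if (iv$start_frame[i] <= cur[2] + 1L) {
          cur[2] <- max(cur[2], iv$end_frame[i])
        } else {
          merged[[length(merged) + 1L]] <- cur
          cur <- c(iv$start_frame[i], iv$end_frame[i])
        }
      }
      merged[[length(merged) + 1L]] <- cur
      nfr <- sum(vapply(merged, function(m) m[2] - m[1] + 1, numeric(1)))
      if (p %in% paws) per_ms[p] <- nfr / frame_rate * 1000
    }
  }
  total <- sum(per_ms)
  list(success = total <= max_contact_ms,
       total_ms = total,
       per_paw = per_ms == 0,
       per_paw_ms = per_ms)
}

#' Hildebrand gait diagram
#'
#' Each stride of the reference limb (touch-down to touch-down) defines a
#' normalised phase axis; every limb's stance indicator is resampled onto a
#' fixed phase grid and averaged across strides, giving the per-limb stance
#' probability as a function of stride phase. In a trot the diagonal limb
#' pairs' stance bands coincide and the two pairs are offset by half a cycle.
#'
#' @param steps A `step_table` (all paws of one session).
#' @param reference Reference limb defining the stride phase.
#' @param n_bins Phase bins.
#' @param only_over_obstacle If `TRUE`, use only reference strides flagged
#'   `is_over_obstacle`.
#' @param min_strides Minimum strides required.
#' @return Object of class `hildebrand`: list with `matrix` (limbs x bins
#'   stance probability), `duty` (per-limb duty factors), `phase` (bin
#'   centres), `n_strides`.
#' @export
hildebrand <- function(steps, reference = "LH", n_bins = 50,
                       only_over_obstacle = FALSE, min_strides = 10) {
  ref <- steps[steps$paw == reference, ]
  if (only_over_obstacle) ref <- ref[ref$is_over_obstacle, ]
  ref <- ref[order(ref$touch_down_frame), ]
  tds <- c(ref$cycle_start_frame, ref$touch_down_frame)
  tds <- sort(unique(tds))
  if (length(tds) - 1L < min_strides)
    stop(sprintf("need at least %d complete strides of %s (have %d)",
                 min_strides, reference, max(0L, length(tds) - 1L)))
  limbs <- unique(steps$paw)
  ## stance indicator per limb over the session span
  span <- c(min(steps$cycle_start_frame), max(steps$touch_down_frame))
  stance_fun <- lapply(limbs, function(p) {
    s <- steps[steps$paw == p, ]
    sw <- rep(FALSE, span[2] - span[1] + 1L)
    for (i in seq_len(nrow(s))) {
      sw[(s$lift_off_frame[i]:(s$touch_down_frame[i] - 1L)) - span[1] + 1L] <- TRUE
    }
    !sw
  })
  names(stance_fun) <- limbs
  mat <- matrix(0, length(limbs), n_bins, dimnames = list(limbs, NULL))
  cnt <- 0L
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  for (k in seq_len(length(tds) - 1L)) {
    f0 <- tds[k]; f1 <- tds[k + 1L]
    if (only_over_obstacle &&
        !any(ref$is_over_obstacle & ref$touch_down_frame > f0 &
               ref$touch_down_frame <= f1)) next
    fr <- pmin(f1 - 1L, f0 + floor(centers * (f1 - f0)))
    idx <- fr - span[1] + 1L
    if (any(idx < 1L) || any(idx > length(stance_fun[[1]]))) next
    for (p in limbs) mat[p, ] <- mat[p, ] + stance_fun[[p]][idx]
    cnt <- cnt + 1L
  }
  if (cnt < min_strides) stop("too few usable strides")
  mat <- mat / cnt
  structure(list(matrix = mat,
                 duty = rowMeans(mat),
                 phase = centers,
                 n_strides = cnt,
                 reference = reference),
            class = "hildebrand")
}

#' @export
print.hildebrand <- function(x, ...) {
  cat(sprintf("<hildebrand> %d strides (reference %s); duty factors:\n",
              x$n_strides, x$reference))
  print(round(x$duty, 3))
  invisible(x)
}

#' @export
plot.hildebrand <- function(x, ...) {
  graphics::image(x$phase, seq_len(nrow(x$matrix)), t(x$matrix),
                  xlab = "stride phase", ylab = "", yaxt = "n",
                  col = grey.colors(64, 1, 0), ...)
  graphics::axis(2, seq_len(nrow(x$matrix)), rownames(x$matrix), las = 1)
  invisible(x)
}

#' Paw-height versus obstacle-height correlation
#'
#' Pearson correlation, per paw, between the paw height measured a fixed
#' distance (8 mm) in front of the obstacle and the obstacle height. Computed
#' for steps over the obstacle and, as a baseline, for control steps (which
#' should show no correlation).
#'
#' @param heights Data frame with columns `paw`, `height_at_8mm`,
#'   `obstacle_height` (one row per trial and paw).
#' @return Named numeric vector of correlations per paw.
#' @export
paw_obstacle_correlation <- function(heights) {
  paws <- unique(heights$paw)
  out <- stats::setNames(numeric(length(paws)), paws)
  for (p in paws) {
    h <- heights[heights$paw == p, ]
    h <- h[stats::complete.cases(h[, c("height_at_8mm", "obstacle_height")]), ]
    if (nrow(h) < 3)
      stop(sprintf("correlation undefined: fewer than 3 trials for %s", p))
    out[p] <- stats::cor(h$height_at_8mm, h$obstacle_height)
  }
  out
}

#' Obstacle position and height per trial
#'
#' In world coordinates the engaged obstacle is stationary; its per-trial
#' position (and height) is taken as the median of the obstacle landmark over
#' the frames just after engagement.
#'
#' @param kin World-frame `obs_kinematics` containing an `obstacle` landmark
#'   and a `trials` table with `engage_frame`.
#' @return Data frame `trial`, `obstacle_x`, `obstacle_z`.
#' @export
trial_obstacle_positions <- function(kin) {
  stopifnot(kin$frame_tag == "world", !is.null(kin$trials))
  tr <- kin$trials
  ox <- kin$positions[, "x", "obstacle"]
  oz <- kin$positions[, "z", "obstacle"]
  f <- function(e) {
    w <- (e + 2L):min(e + 60L, kin$n_frames)
    c(stats::median(ox[w]), stats::median(oz[w]))
  }
  m <- t(vapply(tr$engage_frame, f, numeric(2)))
  data.frame(trial = tr$trial, obstacle_x = m[, 1], obstacle_z = m[, 2])
}

#' Annotate steps crossing the obstacle and measure approach heights
#'
#' Flags, per trial, the step of each paw whose swing crosses the obstacle,
#' records the clearance order (leading/trailing fore/hind), and measures the
#' paw height by linear interpolation at the point a fixed distance in front
#' of the obstacle.
#'
#' @param steps A `step_table` for the session.
#' @param kin World-frame `obs_kinematics`.
#' @param measure_at Distance (mm) in front of the obstacle at which height is
#'   measured.
#' @return List with `steps` (the annotated step table) and `heights` (data
#'   frame `trial`, `paw`, `height_at_8mm`, `obstacle_height`, `order`).
#' @export
annotate_obstacle_steps <- function(steps, kin, measure_at = 8) {
  obs <- trial_obstacle_positions(kin)
  tr <- kin$trials
  hrows <- list()
  for (i in seq_len(nrow(obs))) {
    ox <- obs$obstacle_x[i]
    cross <- numeric(0)
    for (p in unique(steps$paw)) {
      idx <- which(steps$paw == p & steps$lift_off_x < ox &
                     steps$landing_x >= ox &
                     steps$touch_down_frame >= tr$engage_frame[i] &
                     steps$lift_off_frame <= tr$engage_frame[i] + 800L)
      if (length(idx) == 0L) next
      idx <- idx[1]
      steps$is_over_obstacle[idx] <- TRUE
      steps$trial[idx] <- obs$trial[i]
      x <- kin$positions[, "x", p]; z <- kin$positions[, "z", p]
      fr <- steps$lift_off_frame[idx]:steps$touch_down_frame[idx]
      j <- which(x[fr] >= ox - measure_at)[1]
      h8 <- if (is.na(j) || j == 1L) NA_real_ else {
        f2 <- fr[j]; f1 <- fr[j - 1L]
        w <- (ox - measure_at - x[f1]) / (x[f2] - x[f1])
        z[f1] + w * (z[f2] - z[f1])
      }
      cross[p] <- steps$touch_down_frame[idx]
      hrows[[length(hrows) + 1L]] <- data.frame(
        trial = obs$trial[i], paw = p, height_at_8mm = h8,
        obstacle_height = obs$obstacle_z[i],
        cross_frame = steps$touch_down_frame[idx])
    }
  }
  heights <- do.call(rbind, hrows)
  if (!is.null(heights)) {
    heights$order <- NA_character_
    for (t in unique(heights$trial)) {
      h <- heights[heights$trial == t, ]
      fore <- h[h$paw %in% c("LF", "RF"), ]
      hind <- h[h$paw %in% c("LH", "RH"), ]
      lab <- function(d, pre) {
        if (nrow(d) == 0) return()
        o <- order(d$cross_frame)
        heights$order[heights$trial == t &
                        heights$paw == d$paw[o[1]]] <<- paste0("leading_", pre)
        if (nrow(d) > 1)
          heights$order[heights$trial == t &
                          heights$paw == d$paw[o[2]]] <<- paste0("trailing_", pre)
      }
      lab(fore, "fore"); lab(hind, "hind")
    }
  }
  list(steps = steps, heights = heights)
}
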