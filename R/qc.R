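# Tracking post-processing: confidence masking, jump removal, temporal
# median de-spiking, cross-view consistency, interpolation, and the
# un-head-fixing coordinate transform.

#' Post-process a two-view tracking session into clean 3D kinematics
#'
#' Applies, in order: (1) masking of samples with tracking confidence below
#' the threshold, (2) masking of isolated single-frame jumps, (3) temporal
#' median de-spiking, (4) masking of frames where the shared x coordinate
#' disagrees between the two views, and (5) linear interpolation of all
#' masked values. The two views are then merged into 3D positions: the top
#' (side) view contributes x and z, the bottom view x and y, and the shared x
#' is averaged after the consistency check.
#'
#' @param raw An `obs_session` (see [generate_session()] or
#'   [read_session_csv()]).
#' @param qc A [qc_config()].
#' @return An object of class `obs_kinematics`: per-frame 3D positions for
#'   every landmark (array `frames x (x,y,z) x landmark`), the wheel
#'   displacement and velocity traces, and a QC report (masked-sample counts
#'   per landmark and rule) in attribute `"qc_report"`. The coordinate frame
#'   tag is `"head-fixed"`; see [unheadfix()].
#' @export
apply_qc <- function(raw, qc = qc_config()) {
  stopifnot(inherits(raw, "obs_session"))
  tk <- raw$tracking
  n <- raw$n_frames
  landmarks <- unique(tk$landmark)
  views <- c("top", "bottom")
  ## wide matrices per view/coordinate
  get_mat <- function(view, col) {
    sub <- tk[tk$view == view, ]
    m <- matrix(NA_real_, n, length(landmarks), dimnames = list(NULL, landmarks))
    for (lm in landmarks) {
      rows <- sub[sub$landmark == lm, ]
      m[rows$frame, lm] <- rows[[col]]
    }
    m
  }
  xs <- lapply(views, get_mat, col = "x"); names(xs) <- views
  ys <- lapply(views, get_mat, col = "y"); names(ys) <- views
  cf <- lapply(views, get_mat, col = "confidence"); names(cf) <- views

  report <- list()
  mask_counts <- matrix(0L, length(landmarks), 4,
                        dimnames = list(landmarks,
                                        c("confidence", "velocity_jump",
                                          "cross_view", "interpolated")))
  isolated_jump <- function(x, thr) {
    d_prev <- c(NA, abs(diff(x)))
    d_next <- c(abs(diff(x)), NA)
    !is.na(d_prev) & !is.na(d_next) & d_prev > thr & d_next > thr
  }
  for (lm in landmarks) {
    for (v in views) {
      bad <- !is.na(cf[[v]][, lm]) & cf[[v]][, lm] < qc$confidence_threshold
      bad[is.na(xs[[v]][, lm])] <- TRUE
      mask_counts[lm, "confidence"] <- mask_counts[lm, "confidence"] + sum(bad)
      xs[[v]][bad, lm] <- NA; ys[[v]][bad, lm] <- NA
      jump <- isolated_jump(xs[[v]][, lm], qc$velocity_jump_threshold) |
        isolated_jump(ys[[v]][, lm], qc$velocity_jump_threshold)
      mask_counts[lm, "velocity_jump"] <- mask_counts[lm, "velocity_jump"] + sum(jump)
      xs[[v]][jump, lm] <- NA; ys[[v]][jump, lm] <- NA
      tol <- if (qc$median_mode == "full") 0 else qc$median_spike_tol
      xs[[v]][, lm] <- despike_median3(xs[[v]][, lm], tol)
      ys[[v]][, lm] <- despike_median3(ys[[v]][, lm], tol)
    }
    mismatch <- abs(xs$top[, lm] - xs$bottom[, lm]) > qc$cross_view_x_tolerance
    mismatch[is.na(mismatch)] <- FALSE
    mask_counts[lm, "cross_view"] <- sum(mismatch)
    for (v in views) {
      xs[[v]][mismatch, lm] <- NA; ys[[v]][mismatch, lm] <- NA
    }
    miss <- is.na(xs$top[, lm]) | is.na(xs$bottom[, lm])
    mask_counts[lm, "interpolated"] <- sum(miss)
    if (mean(miss) > qc$max_masked_fraction) {
      stop(sprintf("QC failure: %.0f%% of frames masked for landmark '%s'",
                   100 * mean(miss), lm))
    }
    for (v in views) {
      xs[[v]][, lm] <- interp_na(xs[[v]][, lm])
      ys[[v]][, lm] <- interp_na(ys[[v]][, lm])
    }
  }

  pos <- array(NA_real_, c(n, 3, length(landmarks)),
               dimnames = list(NULL, c("x", "y", "z"), landmarks))
  for (lm in landmarks) {
    pos[, "x", lm] <- (xs$top[, lm] + xs$bottom[, lm]) / 2
    pos[, "y", lm] <- ys$bottom[, lm]
    pos[, "z", lm] <- ys$top[, lm]
  }
  wheel_vel <- wheel_velocity(raw$wheel, raw$frame_rate)
  kin <- structure(list(positions = pos,
                        wheel_displacement = raw$wheel,
                        wheel_velocity = wheel_vel,
                        trials = raw$trials,
                        frame_rate = raw$frame_rate,
                        n_frames = n,
                        frame_tag = "head-fixed"),
                   class = "obs_kinematics")
  attr(kin, "qc_report") <- list(masked = mask_counts,
                                 config = unclass(qc))
  kin
}

#' @export
print.obs_kinematics <- function(x, ...) {
  cat(sprintf("<obs_kinematics> %d frames @ %g Hz, %d landmarks, frame: %s\n",
              x$n_frames, x$frame_rate, dim(x$positions)[3], x$frame_tag))
  invisible(x)
}

#' Transform kinematics into un-head-fixed (world) coordinates
#'
#' Adds the wheel displacement to every landmark's x coordinate, so that
#' locomotion is represented as forward travel past a stationary obstacle:
#' stance paws and engaged obstacles become stationary in x. y and z are
#' unchanged. [headfix()] is the exact inverse.
#'
#' @param kin An `obs_kinematics` in the head-fixed frame.
#' @return The same object tagged `"world"`.
#' @export
unheadfix <- function(kin) {
  stopifnot(inherits(kin, "obs_kinematics"))
  if (kin$frame_tag == "world")
    stop("kinematics already in world frame (unheadfix is not idempotent)")
  kin$positions[, "x", ] <- kin$positions[, "x", ] + kin$wheel_displacement
  kin$frame_tag <- "world"
  kin
}

#' @rdname unheadfix
#' @export
headfix <- function(kin) {
  stopifnot(inherits(kin, "obs_kinematics"))
  if (kin$frame_tag == "head-fixed")
    stop("kinematics already in head-fixed frame")
  kin$positions[, "x", ] <- kin$positions[, "x", ] - kin$wheel_displacement
  kin$frame_tag <- "head-fixed"
  kin
}

#' Wheel velocity from the rotary-encoder displacement trace
#'
#' Central-difference differentiation (one-sided at the endpoints) of the
#' displacement trace, with optional moving-average smoothing.
#'
#' @param displacement Displacement trace in mm (one sample per frame).
#' @param frame_rate Hz.
#' @param smooth Optional odd moving-average window in frames (0 = none).
#' @return Velocity trace in m/s.
#' @export
wheel_velocity <- function(displacement, frame_rate, smooth = 0) {
  n <- length(displacement)
  if (n < 3) stop("need at least 3 frames to differentiate")
  dt <- 1 / frame_rate
  v <- numeric(n)
  v[2:(n - 1)] <- (displacement[3:n] - displacement[1:(n - 2)]) / (2 * dt)
  v[1] <- (displacement[2] - displacement[1]) / dt
  v[n] <- (displacement[n] - displacement[n - 1]) / dt
  v <- v / 1000
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    pad <- (smooth - 1) %/% 2
    vv <- stats::filter(c(rep(v[1], pad), v, rep(v[n], pad)), k, sides = 2)
    v <- as.numeric(vv[(pad + 1):(pad + n)])
  }
  v
}

#' Extract a landmark's position matrix
#'
#' @param kin An `obs_kinematics`.
#' @param landmark Landmark name.
#' @return `n_frames x 3` matrix with columns x, y, z (mm).
#' @export
landmark_xyz <- function(kin, landmark) {
  stopifnot(inherits(kin, "obs_kinematics"))
  kin$positions[, , landmark]
}

#' Central-difference velocity of a landmark coordinate
#'
#' @param kin An `obs_kinematics`.
#' @param landmark Landmark name.
#' @param coord `"x"`, `"y"` or `"z"`.
#' @return Velocity trace in m/s.
#' @export
landmark_velocity <- function(kin, landmark, coord = "x") {
  wheel_velocity(kin$positions[, coord, landmark], kin$frame_rate)
}

#' Write the QC report of [apply_qc()] as JSON
#'
#' @param kin An `obs_kinematics` returned by [apply_qc()].
#' @param path Output file.
#' @export
write_qc_report <- function(kin, path) {
  rep <- attr(kin, "qc_report")
  if (is.null(rep)) stop("no QC report attached")
  out <- list(masked = as.data.frame(rep$masked), config = rep$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
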