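# Trial labeling, the logistic shorten/lengthen decision model with
# cross-validation, forward feature selection, shuffled baselines,
# conditional landing-distance heatmaps, and matched-trial comparison.

#' Canonical decision-feature order
#'
#' The eight features measured at whisker contact: horizontal and vertical
#' obstacle position, horizontal and vertical position and velocity of the
#' forepaw in swing, wheel velocity, and body angle. The fixed order also
#' breaks ties in [forward_select()].
#' @export
DECISION_FEATURES <- c("obstacle_x", "obstacle_z", "paw_x", "paw_z",
                       "paw_vx", "paw_vz", "wheel_velocity", "body_angle")

#' Label a trial's step modification
#'
#' A trial is `unmodified` (and discarded from decision modelling) when the
#' paw lands in front of the obstacle within +-`tol` mm of its predicted
#' landing position. Otherwise it is `shortened` when the actual landing falls
#' short of the prediction and `lengthened` when it lands beyond it. Steps
#' over the obstacle require vertical-trajectory modifications and are never
#' `unmodified`, regardless of landing position.
#'
#' @param delta_pred Predicted landing distance (mm, relative to the obstacle,
#'   negative = in front).
#' @param actual Actual landing distance (same convention).
#' @param over_obstacle Logical: did the step clear the obstacle?
#' @param tol Unmodified tolerance (mm).
#' @return Character vector: `"unmodified"`, `"shortened"` or `"lengthened"`.
#' @export
label_modification <- function(delta_pred, actual, over_obstacle = FALSE,
                               tol = 2.5) {
  n <- max(length(delta_pred), length(actual))
  over_obstacle <- rep_len(over_obstacle, n)
  lab <- ifelse(actual < delta_pred, "shortened", "lengthened")
  unmod <- !over_obstacle & actual < 0 & abs(actual - delta_pred) <= tol
  lab[unmod] <- "unmodified"
  lab
}

#' Assemble the per-trial decision dataset of a session
#'
#' For every trial with a known whisker-contact frame: identifies the forepaw
#' in swing at contact (excluding both-swing and both-stance trials), measures
#' the eight decision features at the contact frame, predicts the landing
#' distance from the lift-off position and wheel speed via the session's
#' [fit_landing_model()], determines the actual landing distance, and labels
#' the trial with [label_modification()]. A post-contact stance shorter than
#' `merge_gap_ms` followed by another swing of the same paw is treated as a
#' corrective double-step and merged, the compound step landing at the later
#' touch-down.
#'
#' @param kin World-frame `obs_kinematics`.
#' @param steps A `step_table` for the session (ideally annotated with
#'   [annotate_obstacle_steps()]).
#' @param contact_frames Per-trial whisker-contact frames (same order as
#'   `kin$trials`), e.g. from [consensus_first_contact()] or
#'   [impute_contact_time()].
#' @param landing_model A `landing_model` for the session.
#' @param mouse,condition Identifiers copied into the output.
#' @param merge_gap_ms Corrective-step merge threshold.
#' @return A data frame of class `decision_dataset`: one row per trial with
#'   the eight features, `delta_pred`, `actual`, `label`, `exclusion`,
#'   `is_over_obstacle`, `swing_paw`, `tail_height`, and identifiers.
#' @export
decision_dataset <- function(kin, steps, contact_frames, landing_model,
                             mouse = NA, condition = NA, merge_gap_ms = 24) {
  stopifnot(kin$frame_tag == "world")
  obs <- trial_obstacle_positions(kin)
  tr <- kin$trials
  fr <- kin$frame_rate
  merge_frames <- round(merge_gap_ms / 1000 * fr)
  nose_x <- kin$positions[, "x", "nose"]
  tb <- kin$positions[, , "tail_base"]
  nose_y <- kin$positions[, "y", "nose"]
  vel <- list()
  for (p in c("LF", "RF")) {
    vel[[p]] <- cbind(vx = landmark_velocity(kin, p, "x") * 1000,
                      vz = landmark_velocity(kin, p, "z") * 1000)
  }
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    cf <- contact_frames[i]
    base <- data.frame(trial = tr$trial[i], mouse = mouse, condition = condition,
                       contact_frame = cf, swing_paw = NA_character_,
                       obstacle_x = NA_real_, obstacle_z = NA_real_,
                       paw_x = NA_real_, paw_z = NA_real_,
                       paw_vx = NA_real_, paw_vz = NA_real_,
                       wheel_velocity = NA_real_, body_angle = NA_real_,
                       tail_height = NA_real_,
                       delta_pred = NA_real_, actual = NA_real_,
                       is_over_obstacle = FALSE,
                       label = "excluded", exclusion = NA_character_)
    if (is.na(cf)) { base$exclusion <- "no_contact"; return(base) }
    pw <- paw_in_swing_at_contact(steps, cf)
    if (pw %in% c("BOTH_SWING", "BOTH_STANCE")) {
      base$exclusion <- pw
      return(base)
    }
    s <- steps[steps$paw == pw & steps$lift_off_frame <= cf &
                 cf < steps$touch_down_frame, ]
    if (nrow(s) != 1L) { base$exclusion <- "no_step"; return(base) }
    if (is.na(s$lift_off_x)) { base$exclusion <- "missing_liftoff"; return(base) }
    ox <- obs$obstacle_x[i]
    ## actual landing, merging corrective double-steps
    land_x <- s$landing_x
    land_over <- s$is_over_obstacle
    nxt <- steps[steps$paw == pw & steps$lift_off_frame >= s$touch_down_frame, ]
    if (nrow(nxt) > 0) {
      nxt <- nxt[order(nxt$lift_off_frame), ][1, ]
      if (nxt$lift_off_frame - s$touch_down_frame <= merge_frames) {
        land_x <- nxt$landing_x
        land_over <- land_over || isTRUE(nxt$is_over_obstacle) ||
          (s$lift_off_x < ox && nxt$landing_x >= ox)
      }
    }
    if (s$lift_off_x < ox && land_x >= ox) land_over <- TRUE
    v_c <- kin$wheel_velocity[cf]
    dpred <- predict_landing_distance(s$lift_off_x, v_c, ox, landing_model, pw)
    actual <- land_x - ox
    base$swing_paw <- pw
    base$obstacle_x <- ox - nose_x[cf]
    base$obstacle_z <- obs$obstacle_z[i]
    base$paw_x <- kin$positions[cf, "x", pw] - nose_x[cf]
    base$paw_z <- kin$positions[cf, "z", pw]
    base$paw_vx <- vel[[pw]][cf, "vx"]
    base$paw_vz <- vel[[pw]][cf, "vz"]
    base$wheel_velocity <- v_c
    base$body_angle <- atan2(nose_y[cf] - tb[cf, "y"],
                             nose_x[cf] - tb[cf, "x"]) * 180 / pi
    base$tail_height <- tb[cf, "z"]
    base$delta_pred <- dpred
    base$actual <- actual
    base$is_over_obstacle <- land_over
    base$label <- label_modification(dpred, actual, land_over)
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("decision_dataset", "data.frame")
  out
}

## stratified, seeded fold assignment
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Class-weighted logistic decision model with cross-validation
#'
#' Fits a logistic GLM predicting lengthened versus shortened steps from
#' features measured at whisker contact, with inverse-class-frequency weights
#' to compensate for uneven class sizes, and evaluates it by stratified,
#' seeded k-fold cross-validation (15 folds by default). Features are z-scored
#' across the dataset (within mouse when called per mouse) before fitting.
#'
#' @param data A `decision_dataset` (rows labelled `shortened`/`lengthened`
#'   are used; other labels are dropped).
#' @param features Feature subset (default all eight).
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @param standardize Z-score features before fitting.
#' @param weight_classes Use inverse-class-frequency trial weights.
#' @return Object of class `decision_glm`: coefficients of the final
#'   all-data fit, per-fold accuracies, `mean_accuracy`, class weights and
#'   counts.
#' @export
fit_decision_glm <- function(data, features = DECISION_FEATURES, folds = 15,
                             seed = 1, standardize = TRUE,
                             weight_classes = TRUE) {
  d <- data[data$label %in% c("shortened", "lengthened"), , drop = FALSE]
  y <- as.integer(d$label == "lengthened")
  if (length(unique(y)) < 2L)
    stop("decision dataset contains a single class; cannot fit")
  n_cl <- table(factor(y, levels = 0:1))
  if (min(n_cl) < folds)
    stop(sprintf("need at least %d trials per class for %d-fold CV (have %s)",
                 folds, folds, paste(n_cl, collapse = "/")))
  X <- as.matrix(d[, features, drop = FALSE])
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  if (standardize) X <- scale(X, ctr, scl)
  w <- if (weight_classes) {
    wc <- length(y) / (2 * n_cl)
    as.numeric(wc[as.character(y)])
  } else rep(1, length(y))
  fold <- stratified_folds(y, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- suppressWarnings(stats::glm.fit(cbind(1, X[tr, , drop = FALSE]), y[tr],
                                           weights = w[tr],
                                           family = stats::binomial()))
    eta <- cbind(1, X[!tr, , drop = FALSE]) %*% fit$coefficients
    acc[f] <- mean((eta > 0) == y[!tr])
  }
  final <- suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = w,
                                           family = stats::binomial()))
  coefs <- stats::setNames(final$coefficients, c("(Intercept)", features))
  structure(list(coefficients = coefs,
                 fold_accuracy = acc,
                 mean_accuracy = mean(acc),
                 class_weights = if (weight_classes)
                   stats::setNames(as.numeric(length(y) / (2 * n_cl)),
                                   c("shortened", "lengthened")) else NULL,
                 n_per_class = stats::setNames(as.integer(n_cl),
                                               c("shortened", "lengthened")),
                 features = features, folds = folds, seed = seed,
                 standardize = standardize, center = ctr, scale = scl),
            class = "decision_glm")
}

#' @export
print.decision_glm <- function(x, ...) {
  cat(sprintf("<decision_glm> %d features, %d-fold CV accuracy %.1f%% (n = %d/%d short/length)\n",
              length(x$features), x$folds, 100 * x$mean_accuracy,
              x$n_per_class[1], x$n_per_class[2]))
  invisible(x)
}

#' @export
coef.decision_glm <- function(object, ...) object$coefficients

#' Predict lengthening probability from a fitted decision model
#'
#' @param object A `decision_glm`.
#' @param newdata Data frame containing the model's features.
#' @param ... Unused.
#' @return Probability that the step is lengthened.
#' @export
predict.decision_glm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (object$standardize) X <- scale(X, object$center, object$scale)
  as.numeric(logistic(cbind(1, X) %*% object$coefficients))
}

#' Greedy forward feature selection across mice
#'
#' Starting from the empty model, repeatedly adds the feature whose inclusion
#' yields the greatest mean cross-validated accuracy averaged across mice,
#' until all features are included. Ties are broken by the canonical feature
#' order.
#'
#' @param datasets A list of per-mouse `decision_dataset`s.
#' @param features Candidate features.
#' @param folds,seed CV parameters passed to [fit_decision_glm()].
#' @return Object of class `selection_path`: data frame `feature`,
#'   `mean_accuracy` (cumulative, across mice) in selection order.
#' @export
forward_select <- function(datasets, features = DECISION_FEATURES,
                           folds = 15, seed = 1) {
  selected <- character(0)
  path_acc <- numeric(0)
  remaining <- features
  while (length(remaining)) {
    accs <- vapply(remaining, function(f) {
      mean(vapply(datasets, function(d) {
        fit_decision_glm(d, c(selected, f), folds = folds, seed = seed)$mean_accuracy
      }, numeric(1)))
    }, numeric(1))
    best <- remaining[which.max(accs)]   # ties: first in canonical order
    selected <- c(selected, best)
    path_acc <- c(path_acc, max(accs))
    remaining <- setdiff(remaining, best)
  }
  structure(data.frame(feature = selected, mean_accuracy = path_acc),
            class = c("selection_path", "data.frame"))
}

#' Shuffled-label baseline accuracy
#'
#' Permutes the shorten/lengthen labels and refits the full-feature model
#' under the same CV protocol, establishing the chance-level baseline
#' (expected around 50%).
#'
#' @param data A `decision_dataset`.
#' @param n_shuffles Number of label permutations.
#' @param seed Seed (permutation i uses a substream of it).
#' @param ... Passed to [fit_decision_glm()].
#' @return List with `accuracies`, `mean`, `sd`.
#' @export
shuffled_baseline <- function(data, n_shuffles = 100, seed = 1, ...) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1 (empty distribution)")
  d <- data[data$label %in% c("shortened", "lengthened"), , drop = FALSE]
  acc <- vapply(seq_len(n_shuffles), function(i) {
    d$label <- with_seed(substream_seed(seed, i), sample(d$label))
    fit_decision_glm(d, seed = substream_seed(seed, i), ...)$mean_accuracy
  }, numeric(1))
  list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc))
}

#' Single-hidden-layer network benchmark for the decision model
#'
#' Fits a fully connected network with one hidden layer (100 units by
#' default) under the same stratified CV protocol as [fit_decision_glm()],
#' as a non-linear benchmark. On real data this benchmark performed no
#' better than the logistic model, supporting a relatively simple decision
#' logic.
#'
#' @param data A `decision_dataset`.
#' @param features Feature subset.
#' @param hidden Hidden units.
#' @param folds,seed CV parameters.
#' @return List with `fold_accuracy` and `mean_accuracy`.
#' @export
ann_benchmark <- function(data, features = DECISION_FEATURES, hidden = 100,
                          folds = 15, seed = 1) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stop("the ann benchmark requires the 'nnet' package")
  d <- data[data$label %in% c("shortened", "lengthened"), , drop = FALSE]
  y <- as.integer(d$label == "lengthened")
  X <- scale(as.matrix(d[, features, drop = FALSE]))
  X[, apply(X, 2, function(c) any(!is.finite(c)))] <- 0
  fold <- stratified_folds(y, folds, seed)
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- with_seed(substream_seed(seed, f), {
      utils::capture.output(
        m <- nnet::nnet(X[tr, , drop = FALSE], y[tr], size = hidden,
                        decay = 0.01, maxit = 200, MaxNWts = 5000,
                        entropy = TRUE))
      m
    })
    p <- stats::predict(fit, X[!tr, , drop = FALSE])
    acc[f] <- mean((p > 0.5) == y[!tr])
  }
  list(fold_accuracy = acc, mean_accuracy = mean(acc))
}

#' Conditional landing-distance heatmap
#'
#' Histogram of actual landing distances (rows) within bins of predicted
#' landing distance (columns), each column normalised to sum to one. With an
#' intact decision process the columns are bimodal around the threshold: mass
#' in front of and beyond the obstacle, little at the obstacle itself; without
#' whiskers the distribution collapses onto the unity line.
#'
#' @param delta_pred Predicted landing distances (mm).
#' @param actual Actual landing distances (mm).
#' @param pred_breaks,actual_breaks Strictly increasing bin edges.
#' @return Matrix (length(actual_breaks)-1 rows x length(pred_breaks)-1
#'   columns) of class `landing_heatmap`; empty columns are all-zero.
#' @export
conditional_landing_heatmap <- function(delta_pred, actual,
                                        pred_breaks = seq(-40, 25, by = 5),
                                        actual_breaks = seq(-40, 25, by = 5)) {
  if (any(diff(pred_breaks) <= 0) || any(diff(actual_breaks) <= 0))
    stop("bin edges must be strictly increasing")
  ok <- stats::complete.cases(delta_pred, actual)
  pc <- cut(delta_pred[ok], pred_breaks, include.lowest = TRUE)
  ac <- cut(actual[ok], actual_breaks, include.lowest = TRUE)
  m <- table(ac, pc)
  m <- unclass(m)
  cs <- colSums(m)
  cs[cs == 0] <- 1
  m <- sweep(m, 2, cs, "/")
  structure(m, class = c("landing_heatmap", "matrix"),
            pred_breaks = pred_breaks, actual_breaks = actual_breaks)
}

#' @export
plot.landing_heatmap <- function(x, ...) {
  pb <- attr(x, "pred_breaks"); ab <- attr(x, "actual_breaks")
  graphics::image((pb[-1] + pb[-length(pb)]) / 2, (ab[-1] + ab[-length(ab)]) / 2,
                  t(unclass(x)), xlab = "predicted landing distance (mm)",
                  ylab = "landing distance (mm)", col = grey.colors(64, 1, 0), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Match manipulated trials to control trials on locomotor state
#'
#' Pairs manipulated and control trials of one mouse that are maximally
#' similar in running velocity, body angle and tail height at whisker contact,
#' isolating manipulation effects from locomotor-state differences. Candidate
#' pairs are scored by Euclidean distance in z-scored feature space and
#' selected greedily (lowest distance first, each trial used at most once)
#' until the requested fraction of trials is retained.
#'
#' @param control,manipulated Data frames with the matching feature columns.
#' @param features Matching features.
#' @param fraction Fraction of `min(nrow(control), nrow(manipulated))` pairs
#'   to retain.
#' @return Object of class `matched_trials`: data frame `control_idx`,
#'   `manipulated_idx`, `distance` (row indices into the inputs).
#' @export
match_trials <- function(control, manipulated,
                         features = c("wheel_velocity", "body_angle",
                                      "tail_height"),
                         fraction = 0.2) {
  if (nrow(control) == 0 || nrow(manipulated) == 0)
    stop("both conditions must contain trials")
  all_f <- rbind(control[, features, drop = FALSE],
                 manipulated[, features, drop = FALSE])
  mu <- colMeans(all_f); sg <- apply(all_f, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  zc <- scale(as.matrix(control[, features, drop = FALSE]), mu, sg)
  zm <- scale(as.matrix(manipulated[, features, drop = FALSE]), mu, sg)
  D <- outer(rowSums(zc^2), rowSums(zm^2), "+") - 2 * zc %*% t(zm)
  D[D < 0] <- 0
  n_keep <- floor(fraction * min(nrow(zc), nrow(zm)))
  ord <- order(D)
  used_c <- logical(nrow(zc)); used_m <- logical(nrow(zm))
  out <- list()
  for (o in ord) {
    if (length(out) >= n_keep) break
    i <- (o - 1) %% nrow(zc) + 1
    j <- (o - 1) %/% nrow(zc) + 1
    if (used_c[i] || used_m[j]) next
    used_c[i] <- TRUE; used_m[j] <- TRUE
    out[[length(out) + 1L]] <- data.frame(control_idx = i, manipulated_idx = j,
                                          distance = sqrt(D[i, j]))
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(control_idx = integer(), manipulated_idx = integer(),
               distance = numeric())
  class(res) <- c("matched_trials", "data.frame")
  res
}
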