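test_that("modification labels follow the landing-position rule", {
  ## lands in front, within 2.5 mm of prediction: unmodified
  expect_equal(label_modification(-11, -10), "unmodified")
  ## 10 mm short of prediction: shortened
  expect_equal(label_modification(-5, -15), "shortened")
  ## clears the obstacle: modified regardless of landing position
  expect_equal(label_modification(9, 10, over_obstacle = TRUE), "lengthened")
  expect_equal(label_modification(-11, -10, over_obstacle = TRUE), "lengthened")
  ## beyond prediction and beyond obstacle
  expect_equal(label_modification(-4, 8), "lengthened")
})

test_that("the pipeline recovers every planted label on a simulated session", {
  gs <- medium_sim()
  dd <- medium_decision()
  m <- merge(dd[, c("trial", "label", "swing_paw")],
             gs$truth$trials[, c("trial", "label", "swing_paw", "exclusion")],
             by = "trial")
  mod <- m$label.y %in% c("shortened", "lengthened")
  expect_gt(sum(mod), 15)
  expect_equal(m$label.x[mod], m$label.y[mod])
  expect_equal(m$swing_paw.x[mod], m$swing_paw.y[mod])
  ## both-stance trials are excluded, never labelled
  bs <- !is.na(m$exclusion)
  expect_true(all(m$label.x[bs] == "excluded"))
  ## over-obstacle steps are never unmodified
  expect_false(any(dd$is_over_obstacle & dd$label == "unmodified"))
})

test_that("a linearly separable dataset is classified almost perfectly", {
  set.seed(5)
  n <- 120
  d <- data.frame(matrix(rnorm(n * 8), n, 8))
  names(d) <- DECISION_FEATURES
  d$label <- ifelse(d$obstacle_x + d$paw_x > 0, "lengthened", "shortened")
  class(d) <- c("decision_dataset", "data.frame")
  fit <- fit_decision_glm(d, folds = 10, seed = 1)
  expect_gte(fit$mean_accuracy, 0.95)
  expect_length(fit$fold_accuracy, 10)
  expect_equal(length(coef(fit)), 9)
  ## prediction interface round-trips
  p <- predict(fit, d)
  expect_gt(mean((p > 0.5) == (d$label == "lengthened")), 0.95)
})

test_that("degenerate datasets raise errors", {
  d <- data.frame(matrix(rnorm(80), 10, 8)); names(d) <- DECISION_FEATURES
  d$label <- "shortened"
  expect_error(fit_decision_glm(d), "single class")
  d$label <- rep(c("shortened", "lengthened"), 5)
  expect_error(fit_decision_glm(d, folds = 15), "trials per class")
})

test_that("inverse-frequency weighting equals minority duplication", {
  set.seed(8)
  n <- 90
  d <- data.frame(matrix(rnorm(n * 2), n, 2)); names(d) <- c("f1", "f2")
  y <- c(rep("lengthened", 30), rep("shortened", 60))
  d$label <- y
  class(d) <- c("decision_dataset", "data.frame")
  fw <- fit_decision_glm(d, features = c("f1", "f2"), folds = 5, seed = 1,
                         standardize = FALSE)
  ## duplicate every minority trial once (30 -> 60) and drop the weights
  d2 <- rbind(d, d[d$label == "lengthened", ])
  class(d2) <- c("decision_dataset", "data.frame")
  fu <- fit_decision_glm(d2, features = c("f1", "f2"), folds = 5, seed = 1,
                         standardize = FALSE, weight_classes = FALSE)
  expect_equal(unname(coef(fw)), unname(coef(fu)), tolerance = 1e-6)
})

test_that("fitted weights reproduce the planted decision directions", {
  cfg <- gait_config()
  dd <- do.call(rbind, lapply(1:10, function(s) {
    d <- simulate_decision_dataset(cfg, 400 + s, mouse = "m")
    attributes(d)[c("landing_model", "control_steps", "truth")] <- NULL
    as.data.frame(d)
  }))
  class(dd) <- c("decision_dataset", "data.frame")
  fit <- fit_decision_glm(dd, seed = 1)
  co <- coef(fit)
  ## closer obstacle (smaller obstacle_x) -> more lengthening
  expect_lt(co[["obstacle_x"]], 0)
  ## higher obstacle -> less lengthening
  expect_lt(co[["obstacle_z"]], 0)
  ## paw further forward -> more lengthening (contact early in swing)
  expect_gt(co[["paw_x"]], 0)
})

test_that("shuffled labels fall to chance, deterministically per seed", {
  dd <- medium_decision()
  d <- dd[dd$label %in% c("shortened", "lengthened"), ]
  sb <- shuffled_baseline(d, n_shuffles = 4, seed = 3, folds = 10)
  expect_gt(sb$mean, 0.32)
  expect_lt(sb$mean, 0.68)
  sb2 <- shuffled_baseline(d, n_shuffles = 4, seed = 3, folds = 10)
  expect_identical(sb$accuracies, sb2$accuracies)
  expect_error(shuffled_baseline(d, n_shuffles = 0), "empty")
})

test_that("forward selection finds a planted informative feature first", {
  set.seed(3)
  mk <- function() {
    n <- 200
    d <- data.frame(matrix(rnorm(n * 8), n, 8)); names(d) <- DECISION_FEATURES
    d$label <- ifelse(d$paw_vz + rnorm(n, 0, 0.4) > 0, "lengthened", "shortened")
    class(d) <- c("decision_dataset", "data.frame")
    d
  }
  fs <- forward_select(list(mk(), mk()), folds = 8, seed = 2)
  expect_equal(fs$feature[1], "paw_vz")
  expect_equal(sort(fs$feature), sort(DECISION_FEATURES))
  expect_length(unique(fs$feature), 8)
  ## all-noise features: accuracy path stays near chance
  mk0 <- function() {
    n <- 200
    d <- data.frame(matrix(rnorm(n * 8), n, 8)); names(d) <- DECISION_FEATURES
    d$label <- sample(c("lengthened", "shortened"), n, replace = TRUE)
    class(d) <- c("decision_dataset", "data.frame")
    d
  }
  set.seed(4)
  fs0 <- forward_select(list(mk0(), mk0()), folds = 8, seed = 2)
  expect_true(all(fs0$mean_accuracy > 0.38 & fs0$mean_accuracy < 0.62))
})

test_that("the network benchmark tracks the logistic model on separable data", {
  set.seed(7)
  n <- 150
  d <- data.frame(matrix(rnorm(n * 8), n, 8)); names(d) <- DECISION_FEATURES
  d$label <- ifelse(d$obstacle_x > 0, "lengthened", "shortened")
  class(d) <- c("decision_dataset", "data.frame")
  bm <- ann_benchmark(d, hidden = 10, folds = 5, seed = 1)
  expect_gte(bm$mean_accuracy, 0.9)
})

test_that("the decision boundary recovers the planted threshold at low temperature", {
  cfg <- gait_config(decision_temperature = 0.3, obstacle_height_range = c(7, 7))
  ctx <- sample_decision_contexts(3000, cfg, seed = 5)
  lab <- plant_decision(ctx$delta_pred, ctx$height, cfg,
                        u = with_seed(9, stats::runif(nrow(ctx))))
  fit <- suppressWarnings(stats::glm(I(lab == "lengthened") ~ delta_pred,
                                     data = ctx, family = stats::binomial()))
  boundary <- -stats::coef(fit)[1] / stats::coef(fit)[2]
  theta_eff <- cfg$decision_threshold + cfg$decision_height_coefficient * 7
  expect_lt(abs(boundary - theta_eff), 1)
})

test_that("conditional landing heatmaps are column-normalised histograms", {
  ## actual == predicted: mass on the diagonal
  x <- seq(-35, 20, length.out = 200)
  hm <- conditional_landing_heatmap(x, x)
  m <- unclass(hm)
  expect_true(all(abs(colSums(m)[colSums(m) > 0] - 1) < 1e-12))
  diag_mass <- sum(vapply(seq_len(ncol(m)), function(j) m[j, j], numeric(1)))
  expect_equal(diag_mass, sum(colSums(m) > 0))
  ## a thresholded rule gives bimodal columns near the threshold: mass in
  ## front of and beyond the obstacle, none at the obstacle itself
  set.seed(6)
  pred <- runif(500, -12, -4)
  act <- ifelse(pred > -8, pred + 12, pred - 8)
  hm2 <- unclass(conditional_landing_heatmap(pred, act,
                                             pred_breaks = seq(-15, 0, 5),
                                             actual_breaks = seq(-25, 10, 5)))
  mid <- hm2[, 2]    # predicted bin (-10, -5], straddling the threshold
  expect_gt(mid[2] + mid[3], 0.2)   # shortened mass in front
  expect_gt(mid[6] + mid[7], 0.2)   # lengthened mass beyond
  expect_equal(unname(mid[4] + mid[5]), 0)  # nothing at the obstacle
  ## single trial: one unit cell
  hm1 <- unclass(conditional_landing_heatmap(-7, 3))
  expect_equal(sum(hm1), 1)
  expect_error(conditional_landing_heatmap(1, 1, pred_breaks = c(0, 0, 1)),
               "increasing")
})

test_that("trial matching retains the best pairs and balances the features", {
  ## an exact duplicate is picked first with distance zero
  set.seed(9)
  ctr <- data.frame(wheel_velocity = rnorm(30, 0.55, 0.1),
                    body_angle = rnorm(30, 0, 3),
                    tail_height = rnorm(30, 10, 2))
  man <- ctr[sample(30, 20), ] + matrix(rnorm(60, 0, 0.5), 20, 3)
  man[7, ] <- ctr[3, ]
  mt <- match_trials(ctr, man, fraction = 0.2)
  expect_equal(nrow(mt), floor(0.2 * 20))
  expect_lt(mt$distance[1], 1e-6)
  expect_equal(mt$control_idx[1], 3)
  expect_equal(mt$manipulated_idx[1], 7)
  ## each trial used at most once
  expect_false(any(duplicated(mt$control_idx)))
  expect_false(any(duplicated(mt$manipulated_idx)))
  ## invariant to input ordering (up to the identity of the pairs)
  perm <- sample(nrow(man))
  mt2 <- match_trials(ctr, man[perm, ], fraction = 0.2)
  expect_equal(sort(perm[mt2$manipulated_idx]), sort(mt$manipulated_idx))
  ## matched subsets have closer feature means than the full conditions
  set.seed(10)
  ctr2 <- data.frame(wheel_velocity = rnorm(80, 0.5, 0.1),
                     body_angle = rnorm(80, 0, 3), tail_height = rnorm(80, 10, 2))
  man2 <- data.frame(wheel_velocity = rnorm(80, 0.58, 0.1),
                     body_angle = rnorm(80, 1.5, 3), tail_height = rnorm(80, 9, 2))
  mt3 <- match_trials(ctr2, man2, fraction = 0.2)
  gap_full <- abs(mean(ctr2$wheel_velocity) - mean(man2$wheel_velocity))
  gap_matched <- abs(mean(ctr2$wheel_velocity[mt3$control_idx]) -
                       mean(man2$wheel_velocity[mt3$manipulated_idx]))
  expect_lt(gap_matched, gap_full)
  expect_error(match_trials(ctr2[0, ], man2), "both conditions")
})
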