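test_that("same config and seed give bit-identical sessions", {
  cfg <- small_config()
  a <- generate_session(cfg, seed = 5)
  b <- generate_session(cfg, seed = 5)
  expect_identical(a$session$tracking, b$session$tracking)
  expect_identical(a$session$wheel, b$session$wheel)
  expect_identical(a$truth$trials, b$truth$trials)
})

test_that("trial-level draws are invariant to the number of trials", {
  a <- generate_session(gait_config(n_trials = 4), seed = 9)
  b <- generate_session(gait_config(n_trials = 8), seed = 9)
  cols <- c("obstacle_height", "light", "engage_position_m", "contact_frame",
            "delta_pred_true", "label")
  expect_equal(a$truth$trials[1:4, cols], b$truth$trials[1:4, cols])
})

test_that("noiseless sessions follow the step-length law exactly", {
  gs <- noiseless_sim()
  cfg <- gs$truth$config
  st <- gs$truth$steps
  ctrl <- st[!st$modified & st$paw %in% c("LF", "RF"), ]
  expected <- cfg$step_length_intercept + cfg$step_length_slope * cfg$mean_speed
  expect_true(all(abs(ctrl$length - expected) < 1e-6))
})

test_that("obstacle heights stay inside the configured range and jitters are bounded", {
  tt <- do.call(rbind, lapply(1:5, function(s)
    generate_session(small_config(), seed = s)$truth$trials))
  expect_true(all(tt$obstacle_height >= 4 & tt$obstacle_height <= 10))
  ## engage jitter within +-100 mm of the nominal schedule
  nominal <- ((tt$trial - 1) %/% 3) * 5.4 + c(0.9, 2.7, 4.5)[(tt$trial - 1) %% 3 + 1]
  expect_true(all(abs(tt$engage_position_m - nominal) <= 0.1 + 1e-9))
})

test_that("stance and swing partition every frame for each paw", {
  gs <- default_sim()
  expect_true(all(gs$truth$stance %in% c(TRUE, FALSE)))
  ## trot structure in the noiseless limit: diagonal pairs share stance onsets,
  ## contralateral pairs are offset by half a stride
  ns <- noiseless_sim()
  st <- ns$truth$steps
  td <- function(p) sort(st$td_frame[st$paw == p & !st$modified])
  lf <- td("LF"); rh <- td("RH"); rf <- td("RF")
  nearest <- function(x, ref) vapply(x, function(v) min(abs(ref - v)), numeric(1))
  ## diagonal partner touches down within a frame of LF
  expect_lt(stats::median(nearest(lf, rh)), 1.5)
  ## contralateral forepaw is half a stride away
  stride <- stats::median(diff(lf))
  expect_gt(stats::median(nearest(lf, rf)) / stride, 0.4)
})

test_that("speed regression recovers the planted gait law", {
  gs <- medium_sim()
  tr <- gs$truth
  st <- tr$steps[tr$steps$paw %in% c("LF", "RF") & !tr$steps$modified, ]
  st <- st[st$land_frame <= length(tr$wheel_velocity), ]
  sp <- vapply(seq_len(nrow(st)), function(i)
    mean(tr$wheel_velocity[st$td_frame[i]:st$land_frame[i]]), numeric(1))
  fit <- stats::lm(st$length ~ sp)
  se <- summary(fit)$coefficients[, 2]
  expect_lt(abs(stats::coef(fit)[1] - tr$params$a), 3 * se[1])
  expect_lt(abs(stats::coef(fit)[2] - tr$params$b), 3 * se[2])
  ## closed form: expected absolute residual of the true line is sigma*sqrt(2/pi)
  resid_true <- st$length - (tr$params$a + tr$params$b * sp)
  expect_equal(mean(abs(resid_true)), tr$params$sigma * sqrt(2 / pi),
               tolerance = 0.12)
})

test_that("planted modifications depart exactly at contact + latency", {
  cfg24 <- gait_config(n_trials = 12, planted_latency = 24)
  cfg_off <- gait_config(n_trials = 12, planted_latency = 400)
  g1 <- generate_session(cfg24, seed = 13)
  g2 <- generate_session(cfg_off, seed = 13)
  ok <- g1$truth$trials[!is.na(g1$truth$trials$onset_frame), ]
  expect_gt(nrow(ok), 4)
  for (i in seq_len(nrow(ok))) {
    p <- ok$swing_paw[i]
    d <- which(abs(g1$truth$paw_x_world[, p] - g2$truth$paw_x_world[, p]) > 1e-9 |
                 abs(g1$truth$paw_z[, p] - g2$truth$paw_z[, p]) > 1e-9)
    d <- d[d >= ok$contact_frame[i] & d <= ok$contact_frame[i] + 50]
    expect_equal(d[1], ok$onset_frame[i])
  }
})

test_that("invalid configuration fields raise errors naming the field", {
  expect_error(gait_config(duty_factor = 1.2), "duty_factor")
  expect_error(gait_config(decision_temperature = -1), "decision_temperature")
  expect_error(gait_config(light_on_probability = 2), "light_on_probability")
  expect_error(gait_config(jump_rate = 1.5), "jump_rate")
})

test_that("whisker-contact position correlates with running speed", {
  tt <- do.call(rbind, lapply(1:4, function(s)
    generate_session(gait_config(n_trials = 30), seed = 100 + s)$truth$trials))
  r <- cor(tt$contact_pos_rel_nose, tt$v_contact)
  expect_gt(r, 0.12)
  expect_lt(r, 0.45)
})

test_that("decision-context sampler matches the realized session distribution", {
  cfg <- gait_config(n_trials = 30)
  tt <- do.call(rbind, lapply(1:4, function(s)
    generate_session(cfg, seed = 200 + s)$truth$trials))
  tt <- tt[is.na(tt$exclusion), ]
  ctx <- sample_decision_contexts(5e4, cfg, seed = 1)
  expect_lt(abs(mean(tt$delta_pred_true) - mean(ctx$delta_pred)), 2)
  expect_lt(abs(stats::sd(tt$delta_pred_true) - stats::sd(ctx$delta_pred)), 1.5)
})
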