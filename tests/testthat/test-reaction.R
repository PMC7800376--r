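test_that("kNN matching equals an exhaustive distance sort", {
  set.seed(12)
  m <- 8
  query <- cbind(x = cumsum(runif(m, 2, 6)), z = runif(m, 0, 10))
  pool <- lapply(1:200, function(i)
    cbind(x = cumsum(runif(m, 2, 6)), z = runif(m, 0, 10)))
  idx <- match_control_steps(query, pool, k = 40)
  oracle <- order(vapply(pool, function(p) sum((p - query)^2), numeric(1)))[1:40]
  expect_equal(sort(idx), sort(oracle))
  expect_equal(as.integer(idx[1]), oracle[1])
  ## a pool of exactly k returns everything; identical query ranks first
  expect_equal(sort(match_control_steps(query, pool[1:40], k = 40)), 1:40)
  pool2 <- c(pool, list(query))
  best <- match_control_steps(query, pool2, k = 5)
  expect_equal(as.integer(best[1]), 201L)
  expect_equal(attr(best, "distance")[1], 0)
  expect_error(match_control_steps(query, pool[1:10], k = 40), "pool too small")
})

test_that("deviation traces are zero for the family mean and 1 for a 1-SD offset", {
  set.seed(13)
  W <- 20
  fam <- lapply(1:40, function(i) cbind(x = cumsum(runif(W, 2, 4)),
                                        z = rnorm(W, 5, 1)))
  arr <- array(unlist(fam), c(W, 2, 40))
  fmean <- apply(arr, c(1, 2), mean)
  fsd <- apply(arr, c(1, 2), sd)
  tr0 <- deviation_trace(fmean, fam, contact_index = 5)
  expect_true(all(abs(tr0$norm) < 1e-10))
  tr1 <- deviation_trace(fmean + fsd, fam, contact_index = 5)
  expect_true(all(abs(tr1$norm - 1) < 1e-10))
})

test_that("onset detection follows the threshold rule", {
  W <- 30; ci <- 10
  mk <- function(norm) structure(list(norm = norm, contact_index = ci),
                                 class = "deviation_trace")
  ## never crossed: no latency
  expect_true(is.na(onset_latency(mk(rep(1, W)))))
  ## a 5-SD step change 6 frames after contact: 24 ms at 250 Hz
  nrm <- rep(0.3, W); nrm[(ci + 6):W] <- 5
  expect_equal(onset_latency(mk(nrm)), 24)
  ## threshold zero: latency zero
  cfg0 <- reaction_config(deviation_threshold = 1e-12)
  expect_equal(onset_latency(mk(rep(1, W)), cfg0), 0)
  ## a single-frame excursion is rejected by the 2-frame sustain rule
  spike <- rep(0.3, W); spike[ci + 3] <- 5; spike[(ci + 8):W] <- 5
  expect_equal(onset_latency(mk(spike)), 8 / 250 * 1000)
  ## monotonicity: raising the threshold never decreases the latency
  set.seed(14)
  for (i in 1:20) {
    nrm <- cumsum(abs(rnorm(W, 0.2)))
    lats <- vapply(c(1, 2.5, 4, 8), function(th)
      onset_latency(mk(nrm), reaction_config(deviation_threshold = th)),
      numeric(1))
    lats <- lats[!is.na(lats)]
    expect_true(all(diff(lats) >= 0))
  }
})

test_that("planted reaction latencies are recovered on simulated sessions", {
  gs <- medium_sim()
  pl <- medium_pipeline()
  tt <- gs$truth$trials
  tri <- data.frame(trial = tt$trial, contact_frame = tt$contact_frame,
                    swing_paw = tt$swing_paw)
  re <- reaction_latencies(pl$kin, pl$steps, tri)
  expect_gt(re$n_eligible, 10)
  expect_gt(re$detection_rate, 0.8)
  expect_lt(abs(re$median_latency_ms - 24), 4)
})

test_that("control steps show no deviation and no false onsets", {
  gs <- medium_sim()
  pl <- medium_pipeline()
  tt <- gs$truth$trials
  tri <- data.frame(trial = tt$trial, contact_frame = tt$contact_frame,
                    swing_paw = tt$swing_paw)
  cv <- control_validation(pl$kin, pl$steps, tri)
  expect_gt(cv$n, 10)
  expect_lt(abs(cv$mean_dev_mm[["x"]]), 1.5)
  expect_lt(abs(cv$mean_dev_mm[["z"]]), 1)
  expect_lt(cv$false_onset_rate, 0.15)
})

test_that("time to contact extrapolates the anterior paw trajectory", {
  ## noiseless construction: anterior paw 20 mm from the obstacle closing at
  ## 0.5 m/s -> 40 ms
  n <- 150
  pos <- array(0, c(n, 3, 4), dimnames = list(NULL, c("x", "y", "z"),
                                              c("LF", "RF", "LH", "RH")))
  pos[, "x", "LF"] <- 500 * (seq_len(n) / 250)      # 0.5 m/s
  pos[, "x", "RF"] <- pos[, "x", "LF"] - 30
  kin <- structure(list(positions = pos, frame_rate = 250, n_frames = n,
                        frame_tag = "world"), class = "obs_kinematics")
  obstacle_x <- pos[n, "x", "LF"] + 20              # 20 mm ahead at contact
  ttc <- time_to_contact(kin, contact_frame = n, obstacle_x = obstacle_x)
  expect_equal(as.numeric(ttc), 40, tolerance = 0.02)
  ## not approaching: flagged NA
  kin2 <- kin
  kin2$positions[, "x", c("LF", "RF", "LH", "RH")] <-
    -kin$positions[, "x", c("LF", "RF", "LH", "RH")]
  expect_true(is.na(time_to_contact(kin2, n, 100)))
  expect_error(time_to_contact(kin, 50, 100), "frames before contact")
  ## simulated cohort: same order of magnitude as whisker-to-paw distances
  gs <- medium_sim()
  pl <- medium_pipeline()
  obs <- trial_obstacle_positions(pl$kin)
  tt <- gs$truth$trials
  ttc_all <- vapply(seq_len(nrow(tt)), function(i)
    as.numeric(time_to_contact(pl$kin, tt$contact_frame[i], obs$obstacle_x[i])),
    numeric(1))
  expect_gt(mean(ttc_all, na.rm = TRUE), 25)
  expect_lt(mean(ttc_all, na.rm = TRUE), 75)
})
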