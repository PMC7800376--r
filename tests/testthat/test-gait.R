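test_that("stance rule applies both tolerances and the debounce", {
  cfg <- stance_config()
  ## within 0.2 m/s of zero world speed and within 5 mm of the surface: stance
  expect_true(detect_stance(rep(3, 20), rep(0.1, 20), cfg)[10])
  ## too high: swing, whatever the velocity
  expect_false(detect_stance(rep(6, 20), rep(0, 20), cfg)[10])
  ## one-frame blip is removed by the 5-frame median at 250 Hz
  z <- rep(0, 30); v <- rep(0, 30); v[15] <- 1
  st <- detect_stance(z, v, cfg, 250)
  expect_true(all(st))
  ## brute-force median-filter oracle on a random boolean trace
  raw <- with_seed(2, runif(200) > 0.3)
  deb <- detect_stance(ifelse(raw, 0, 10), rep(0, 200), cfg, 250)
  oracle <- sapply(1:200, function(i) {
    w <- max(1, i - 2):min(200, i + 2)
    w <- c(w, rep(1, 2 - (i - max(1, i - 2))), rep(200, 2 - (min(200, i + 2) - i)))
    mean(raw[w]) > 0.5
  })
  expect_equal(deb, oracle)
  expect_error(detect_stance(1:5, 1:4), "length")
  ## camera-frame accessor: stance paw moves at minus wheel speed
  wheel <- rep(0.5, 30)
  expect_true(all(detect_stance_camera(rep(0, 30), rep(-0.5, 30), wheel, cfg)))
})

test_that("square-wave stance segments into the expected steps", {
  stance <- rep(rep(c(TRUE, FALSE), times = c(24, 16)), 10)
  x <- cumsum(rep(1, length(stance)))
  st <- segment_steps(stance, x, rep(0, length(stance)), paw = "LF")
  expect_true(all(st$touch_down_frame - st$lift_off_frame == 16))
  expect_gt(nrow(st), 5)
  expect_true(all(st$length > 0))
  ## all-stance: nothing to segment
  expect_equal(nrow(segment_steps(rep(TRUE, 100), x[1:100], rep(0, 100))), 0)
})

test_that("segmentation inverts the simulator schedule frame-exactly in the noiseless limit", {
  gs <- noiseless_sim()
  pl <- session_pipeline(gs)
  sm <- attr(pl$steps, "stance")
  ## frames inside a modification window may legitimately differ (corrective
  ## re-steps have sub-debounce stance gaps); everything else is exact
  tt <- gs$truth$trials
  mod_mask <- matrix(FALSE, nrow(sm), 4, dimnames = dimnames(sm))
  for (i in which(!is.na(tt$onset_frame))) {
    fr <- max(1, tt$contact_frame[i]):min(nrow(sm), tt$onset_frame[i] + 40)
    mod_mask[fr, tt$swing_paw[i]] <- TRUE
  }
  for (p in c("LF", "RF", "LH", "RH")) {
    out <- !mod_mask[, p]
    expect_identical(unname(sm[out, p]), unname(gs$truth$stance[out, p]))
  }
  for (p in c("LF", "RF")) {
    tl <- gs$truth$steps[gs$truth$steps$paw == p, ]
    sl <- pl$steps[pl$steps$paw == p, ]
    ## unmodified steps: boundaries and lengths exact
    un <- merge(tl[!tl$modified, ], sl, by.x = "lo_frame", by.y = "lift_off_frame")
    expect_gt(nrow(un), sum(!tl$modified) - 4)
    expect_equal(un$land_frame, un$touch_down_frame)
    expect_equal(un$length.x, un$length.y, tolerance = 1e-10)
    ## modified steps: the detected step in flight just after the onset lands
    ## exactly at the planted modified landing position
    for (i in which(!is.na(tt$onset_frame) & tt$swing_paw == p)) {
      s_i <- sl[sl$lift_off_frame <= tt$onset_frame[i] + 1 &
                  sl$touch_down_frame > tt$onset_frame[i] + 1, ]
      expect_equal(nrow(s_i), 1)
      expect_equal(s_i$landing_x, tt$modified_landing_x[i], tolerance = 1e-8)
    }
  }
})

test_that("control steps are the two latest before contact", {
  steps <- data.frame(paw = "LF", cycle_start_frame = seq(1, 161, 40),
                      lift_off_frame = seq(25, 185, 40),
                      touch_down_frame = seq(40, 200, 40),
                      lift_off_x = 0, landing_x = 55, length = 55,
                      peak_height = 10, speed = 0.5, duration_ms = 60,
                      is_control = FALSE, is_over_obstacle = FALSE,
                      trial = NA_integer_)
  got <- control_steps(steps, contact_frame = 1000, paw = "LF")
  expect_equal(got$touch_down_frame, c(200, 160))
  expect_true(all(got$is_control))
  expect_warning(one <- control_steps(steps, contact_frame = 50, paw = "LF"),
                 "control step")
  expect_equal(nrow(one), 1)
  expect_true(isTRUE(attr(one, "insufficient")))
  expect_warning(none <- control_steps(steps, contact_frame = 10, paw = "LF"),
                 "control step")
  expect_equal(nrow(none), 0)
})

test_that("the forepaw in swing at contact is identified, with exclusion codes", {
  steps <- rbind(
    data.frame(paw = "LF", cycle_start_frame = 1, lift_off_frame = 10,
               touch_down_frame = 20, lift_off_x = 0, landing_x = 55,
               length = 55, peak_height = 10, speed = 0.5, duration_ms = 40,
               is_control = FALSE, is_over_obstacle = FALSE, trial = NA_integer_),
    data.frame(paw = "RF", cycle_start_frame = 1, lift_off_frame = 30,
               touch_down_frame = 40, lift_off_x = 0, landing_x = 55,
               length = 55, peak_height = 10, speed = 0.5, duration_ms = 40,
               is_control = FALSE, is_over_obstacle = FALSE, trial = NA_integer_))
  expect_equal(paw_in_swing_at_contact(steps, 15), "LF")
  expect_equal(paw_in_swing_at_contact(steps, 35), "RF")
  expect_equal(paw_in_swing_at_contact(steps, 25), "BOTH_STANCE")
  both <- steps; both$lift_off_frame <- 10; both$touch_down_frame <- 20
  expect_equal(paw_in_swing_at_contact(both, 15), "BOTH_SWING")
})

test_that("trial success matches the contact-duration rule and a brute-force oracle", {
  iv <- function(p, s, e) data.frame(paw = p, start_frame = s, end_frame = e)
  ## 16 ms (4 frames at 250 Hz): success
  expect_true(trial_success(iv("LF", 10, 13))$success)
  ## 24 ms: failure
  expect_false(trial_success(iv("LF", 10, 15))$success)
  ## exactly 20 ms: success (inclusive)
  expect_true(trial_success(iv("LF", 10, 14))$success)
  ## overlapping intervals merge before summation
  res <- trial_success(rbind(iv("LF", 10, 14), iv("LF", 12, 16)))
  expect_equal(res$total_ms, 7 / 250 * 1000)
  expect_false(res$per_paw[["LF"]])
  expect_true(res$per_paw[["RF"]])
  ## brute-force frame-count oracle on random interval sets
  for (rep in 1:25) {
    ns <- with_seed(rep, sample(0:5, 1))
    if (ns == 0) { contacts <- iv(character(0), integer(0), integer(0))
    } else {
      contacts <- with_seed(rep * 7, {
        s <- sample(1:80, ns, replace = TRUE)
        data.frame(paw = sample(c("LF", "RF", "LH", "RH"), ns, replace = TRUE),
                   start_frame = s, end_frame = s + sample(0:8, ns, replace = TRUE))
      })
    }
    res <- trial_success(contacts)
    frames <- unique(do.call(rbind, lapply(seq_len(nrow(contacts)), function(i)
      data.frame(paw = contacts$paw[i],
                 f = contacts$start_frame[i]:contacts$end_frame[i]))))
    oracle_ms <- if (is.null(frames)) 0 else nrow(frames) / 250 * 1000
    expect_equal(res$total_ms, oracle_ms)
    expect_equal(res$success, oracle_ms <= 20)
  }
})

test_that("Hildebrand diagrams show a trot with the configured duty factor", {
  gs <- noiseless_sim()
  pl <- session_pipeline(gs)
  hb <- hildebrand(pl$steps, reference = "LH", n_bins = 50)
  expect_true(all(hb$matrix >= 0 & hb$matrix <= 1))
  ## duty factors within one bin width of the configured 0.6
  expect_true(all(abs(hb$duty - 0.6) < 0.04))
  ## diagonal pair bands coincide; contralateral pair offset by half a cycle
  cor_diag <- cor(hb$matrix["LH", ], hb$matrix["RF", ])
  shift <- hb$matrix["RH", c(26:50, 1:25)]
  cor_anti <- cor(hb$matrix["LH", ], shift)
  expect_gt(cor_diag, 0.9)
  expect_gt(cor_anti, 0.9)
  ## single-limb input reduces to that limb's duty profile
  hb1 <- hildebrand(pl$steps[pl$steps$paw == "LH", ], reference = "LH")
  expect_equal(rownames(hb1$matrix), "LH")
  expect_true(abs(hb1$duty - 0.6) < 0.04)
  expect_error(hildebrand(pl$steps[1:8, ], reference = "LF"), "strides")
})

test_that("paw/obstacle height correlations behave at the limits", {
  h <- data.frame(paw = "LF", obstacle_height = c(4, 6, 8, 10),
                  height_at_8mm = c(4, 6, 8, 10) + 3)
  expect_equal(unname(paw_obstacle_correlation(h)["LF"]), 1)
  set.seed(2)
  h2 <- data.frame(paw = "RF", obstacle_height = runif(40, 4, 10),
                   height_at_8mm = rnorm(40, 10))
  expect_lt(abs(paw_obstacle_correlation(h2)["RF"]), 0.35)
  expect_error(paw_obstacle_correlation(h[1:2, ]), "fewer than 3")
})

test_that("obstacle-step annotation tracks obstacle height and matches an oracle", {
  gs <- medium_sim()
  pl <- medium_pipeline()
  hh <- pl$heights
  expect_gt(nrow(hh), 40)
  r <- paw_obstacle_correlation(hh)
  expect_true(all(r > 0))
  ## oracle: correlation recomputed directly from the same planted values
  for (p in unique(hh$paw)) {
    sub <- hh[hh$paw == p & complete.cases(hh[, c("height_at_8mm", "obstacle_height")]), ]
    expect_equal(unname(r[p]), cor(sub$height_at_8mm, sub$obstacle_height))
  }
  ## clearance order labels exist for fore and hind girdles
  expect_true(any(hh$order == "leading_fore", na.rm = TRUE))
  expect_true(any(hh$order == "trailing_hind", na.rm = TRUE))
})
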