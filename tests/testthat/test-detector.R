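# stage two: reference template, NSRP features, the time-continuous loop

test_that("reference template reads off mid-hip and torso length at stable frames", {
  fr <- make_frame(cx = 100, cy = 200, torso = 100)
  xi <- update_template(fr, "STABLE")
  expect_equal(c(xi$Px, xi$Py, xi$H), c(100, 200, 100))
  fr2 <- make_frame(cx = 130, cy = 190, torso = 100)
  xi2 <- update_template(fr2, "STABLE")   # last writer wins
  expect_equal(c(xi2$Px, xi2$Py), c(130, 190))
  expect_error(update_template(fr, "FLUCTUATING"), "STABLE")
})

test_that("centroid increment matches the softsign formula evaluated by hand", {
  xi <- update_template(make_frame(cx = 100, cy = 200), "STABLE")
  expect_equal(centroid_increment(xi, make_frame(cx = 100, cy = 200)), 0)
  # displacement (0, +50) down-image: softsign(-50) * 50 / 100
  mu_down <- centroid_increment(xi, make_frame(cx = 100, cy = 250))
  expect_equal(mu_down, (-50 / 51) * (50 / 100), tolerance = 1e-12)
  expect_equal(mu_down, -0.49020, tolerance = 1e-4)
  # displacement (30, -40) up-image: softsign(+40) * 50 / 100
  mu_up <- centroid_increment(xi, make_frame(cx = 130, cy = 160))
  expect_equal(mu_up, (40 / 41) * (50 / 100), tolerance = 1e-12)
  expect_equal(mu_up, 0.48780, tolerance = 1e-4)
  # strict-sign variant keeps magnitude, hardens direction
  expect_equal(centroid_increment(xi, make_frame(cx = 100, cy = 250),
                                  soft_sign = FALSE), -0.5)
  expect_error(centroid_increment(NULL, make_frame()), "not set")
})

test_that("compare value is a plain sum with empty sum zero", {
  expect_equal(compare_value(numeric(0)), 0)
  expect_equal(compare_value(c(0, 0, 0)), 0)
  expect_equal(compare_value(c(-0.4901961, -0.4901961)), -0.9803922,
               tolerance = 1e-6)
})

test_that("energy value measures lower-limb vertical dispersion over the template scale", {
  xi <- update_template(make_frame(torso = 100), "STABLE")
  f1 <- make_frame(); f2 <- make_frame()
  expect_equal(energy_value(list(f1, f2), xi), 0)  # all ys constant
  f2$keypoints[11, "y"] <- f1$keypoints[11, "y"] + 10  # keypoint 10
  expect_equal(energy_value(list(f1, f2), xi), (5 + 5) / 100)
  # scale invariance: double all coordinates and H
  g1 <- f1; g2 <- f2
  g1$keypoints[, 1:2] <- 2 * g1$keypoints[, 1:2]
  g2$keypoints[, 1:2] <- 2 * g2$keypoints[, 1:2]
  xi2 <- xi; xi2$H <- 200
  expect_equal(energy_value(list(g1, g2), xi2),
               energy_value(list(f1, f2), xi))
  # translation in y leaves deviations unchanged
  h1 <- f1; h2 <- f2
  h1$keypoints[, 2] <- h1$keypoints[, 2] + 37
  h2$keypoints[, 2] <- h2$keypoints[, 2] + 37
  expect_equal(energy_value(list(h1, h2), xi), energy_value(list(f1, f2), xi))
  expect_error(energy_value(list(), xi), "empty")
})

test_that("state score accumulates 0/1/2 per state", {
  expect_equal(state_score(rep("DISORDER", 10)), 20)
  expect_equal(state_score(rep("FLUCTUATING", 10)), 10)
  expect_equal(state_score(c("STABLE", "FLUCTUATING", "DISORDER")), 3)
  expect_equal(state_score(character(0)), 0)
})

test_that("the detector never fires on stable streams and aborts on sustained recovery", {
  seq <- standing_sequence(xs = rep(160, 200), ys = rep(120, 200))
  st <- state_stream(key_feature_table(seq))
  expect_equal(st$state, rep("STABLE", 200))
  expect_equal(nrow(run_detector(seq, st)), 0L)

  # 3 unstable frames open an NSRP but 3 stable frames abort it
  states <- states_df(c(rep("STABLE", 5), rep("FLUCTUATING", 3),
                        rep("STABLE", 20)))
  seq2 <- standing_sequence(xs = rep(160, 28), ys = rep(120, 28))
  expect_equal(nrow(run_detector(seq2, states)), 0L)
})

test_that("a sustained disorder with descending mid-hip yields one event with tau 20 and negative gamma", {
  n <- 113
  ys <- c(rep(120, 100), 120 + cumsum(rep(7, 13)))
  seq <- standing_sequence(xs = rep(160, n), ys = ys)
  states <- states_df(c(rep("STABLE", 100), rep("DISORDER", 13)))
  ev <- run_detector(seq, states)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$tau, 20)
  expect_lt(ev$gamma, 0)
  expect_gt(ev$epsilon, 0)
  expect_true(is.na(ev$is_fall))
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 112)

  # a monotonically ascending mid-hip gives strictly positive gamma
  seq_up <- standing_sequence(xs = rep(160, n),
                              ys = c(rep(120, 100), 120 - cumsum(rep(7, 13))))
  expect_gt(run_detector(seq_up, states)$gamma, 0)
})

test_that("events never overlap and are at most one per window span", {
  set.seed(21)
  for (rep in 1:20) {
    s <- random_stream(80, seed = 5000 + rep)
    ev <- run_detector(s$seq, s$states)
    if (nrow(ev) >= 2) {
      expect_true(all(ev$start_frame[-1] > ev$end_frame[-nrow(ev)]))
    }
    cfg <- detector_config()
    expect_true(all(ev$end_frame - ev$start_frame + 1 >=
                    cfg$unstable_run + cfg$nsrp_window))
  }
})

test_that("replaying a stream yields identical events", {
  s <- random_stream(120, seed = 99)
  expect_identical(run_detector(s$seq, s$states),
                   run_detector(s$seq, s$states))
})

test_that("the detector matches a literal-transcription oracle, including the trigger-inclusive variant", {
  for (rep in 1:60) {
    s <- random_stream(sample(20:80, 1), seed = 7000 + rep)
    expect_equal(run_detector(s$seq, s$states), oracle_detect(s$seq, s$states),
                 tolerance = 1e-12, label = paste("stream", rep))
    cfg <- detector_config(include_trigger = TRUE)
    expect_equal(run_detector(s$seq, s$states, cfg = cfg),
                 oracle_detect(s$seq, s$states, cfg),
                 tolerance = 1e-12, label = paste("stream+trigger", rep))
  }
})

test_that("classifier failures propagate with the frame span attached", {
  n <- 113
  seq <- standing_sequence(xs = rep(160, n), ys = rep(120, n))
  states <- states_df(c(rep("STABLE", 100), rep("DISORDER", 13)))
  broken <- structure(list(), class = "fall_classifier")
  suppressWarnings(
    expect_error(run_detector(seq, states, model = broken), "frames 100-112"))
})

test_that("events serialise to JSON lines", {
  ev <- data.frame(start_frame = 5L, end_frame = 17L, gamma = -3.25,
                   epsilon = 1.5, tau = 18L, is_fall = TRUE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_events(ev, path)
  back <- jsonlite::fromJSON(readLines(path))
  expect_equal(back$gamma, -3.25)
  expect_true(back$is_fall)
})
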