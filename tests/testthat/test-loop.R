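test_that("settling time implements entry, dwell and re-entry rules", {
  crit <- settling_criterion("svm")
  expect_equal(as.numeric(settling_time(c(1.0, 0.6, 0.3, 0.3, 0.3), crit)), 2)
  expect_true(is.na(settling_time(c(1, 0.9, 0.8), crit)))
  # enters at 1 s, exits at 3 s, re-enters at 4 s through the end -> 4 s
  expect_equal(as.numeric(settling_time(c(1, 0.3, 0.3, 0.5, 0.3), crit)), 4)
  # windowed dwell accepts the first sustained entry
  crit3 <- settling_criterion("svm", dwell_hops = 2)
  expect_equal(as.numeric(settling_time(c(1, 0.3, 0.3, 0.5, 0.3), crit3)), 1)
  expect_equal(settling_criterion("gmm")$interval, c(1e-8, 0.1))
  expect_error(settling_time(numeric(), crit), "empty")
})

test_that("the stimulation clamp holds under a saturating policy", {
  p <- test_profile()
  m <- train_state_estimator(p, "svm", seed = p$seed)
  traj <- run_closed_loop(p, m, function(state, dstate) 60,
                          loop_config(duration_s = 8, hop_s = 1,
                                      control_period_s = 1, warmup = "full",
                                      seed = 3))
  expect_equal(traj$f_hz[1:4], c(60, 120, 180, 180))
  expect_true(all(traj$f_hz >= 0 & traj$f_hz <= 180))
})

test_that("without control the PD state stays parkinsonian", {
  p <- test_profile()
  m <- train_state_estimator(p, "svm", seed = p$seed)
  traj <- run_closed_loop(p, m, function(state, dstate) 0,
                          loop_config(duration_s = 10, seed = 5))
  expect_true(all(traj$p > 0.5))
})

test_that("closed-loop runs are deterministic and structurally sound", {
  p <- test_profile()
  m <- train_state_estimator(p, "svm", seed = p$seed)
  cs <- fuzzy_controller_svm()
  cfg <- loop_config(duration_s = 10, seed = 17)
  t1 <- run_closed_loop(p, m, cs, cfg)
  t2 <- run_closed_loop(p, m, cs, cfg)
  expect_identical(t1, t2)
  expect_true(all(is.finite(t1$p)) && all(t1$p >= 0 & t1$p <= 1))
  expect_true(all(is.finite(t1$f_hz)))
  expect_true(all(abs(t1$df_hz) <= 60))
  expect_error(run_closed_loop(p, m, fuzzy_controller_gmm(), cfg),
               "does not match")
})

test_that("a separable profile suppresses into the modal interval", {
  p <- test_profile(separability = 1.2, seed = 31)
  m <- train_state_estimator(p, "svm", seed = p$seed)
  traj <- run_closed_loop(p, m, fuzzy_controller_svm(),
                          loop_config(duration_s = 25, seed = 31))
  st <- settling_time(traj, settling_criterion("svm", dwell_hops = 3))
  expect_false(is.na(st))
  idx <- traj$t_s - traj$t_s[1] >= st
  expect_gt(median(traj$p[idx]), 0.15)
  expect_lt(median(traj$p[idx]), 0.35)
  # increasing stimulation never pushes features back toward the PD centroid
  mc <- profile_modulation_config(p)
  g <- gain_for_frequency(mc, seq(0, 180, 10), 1)
  expect_true(all(diff(g) >= 0))
})

test_that("profile characterization maps state and offset to state change", {
  p <- test_profile(seed = 41)
  m <- train_state_estimator(p, "svm", seed = p$seed)
  grid <- characterize_profile(p, m, n_epochs = 4L, seed = 41)
  expect_equal(dim(grid), c(11L, 19L))
  zero_col <- grid[, "df+0"]
  expect_true(all(abs(zero_col[!is.na(zero_col)]) < 1e-9))
  # at mid severity a +45 Hz offset pushes the state toward non-PD
  v <- grid["p0.5", "df+45"]
  if (!is.na(v)) expect_lt(v, 0)
})
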