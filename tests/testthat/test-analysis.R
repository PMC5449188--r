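test_that("saccade detection finds one event of the commanded size", {
  traj <- canonical_saccade()
  ev <- detect_saccades(traj)
  expect_equal(nrow(ev), 1)
  expect_gt(ev$amplitude, 19)
  expect_lt(ev$amplitude, 21)
  expect_gt(ev$peak_velocity, 300)
  expect_lt(ev$duration, 0.1)
  expect_lt(ev$onset, ev$offset)

  # raising the threshold above peak velocity empties the list
  expect_equal(nrow(detect_saccades(traj, v_threshold = 1000)), 0)
})

test_that("brief sub-threshold gaps are merged into one event", {
  tr <- tibble::tibble(
    time = seq(0, 0.2, by = 0.005),
    eye_vel = 0, eye_pos = cumsum(rep(0, 41))
  )
  tr$eye_vel[11:20] <- 100
  tr$eye_vel[22:26] <- 100 # 5 ms dip at sample 21
  tr$eye_pos <- cumsum(tr$eye_vel) * 0.005
  ev <- detect_saccades(tr)
  expect_equal(nrow(ev), 1)
  # a 15 ms gap is not merged
  tr$eye_vel[22:26] <- 0
  tr$eye_vel[25:30] <- 100
  tr$eye_vel[22:24] <- 0
  ev2 <- detect_saccades(tr)
  expect_equal(nrow(ev2), 2)
})

test_that("suppression window brackets the saccade and shifts by the delay", {
  traj <- canonical_saccade()
  rep_ <- suppression_window(traj)
  expect_true(rep_$suppressed)
  expect_gt(rep_$relative_drop, 0.5)
  expect_lt(rep_$relative_drop, 1)
  expect_lt(abs(rep_$onset_timelocked), 0.010)
  expect_gt(rep_$offset_timelocked, 0.140)
  expect_lt(rep_$offset_timelocked, 0.160)
  # stimulus-locked bounds are the time-locked bounds minus the delay, exactly
  expect_equal(rep_$onset_stimlocked, rep_$onset_timelocked - 0.1)
  expect_equal(rep_$offset_stimlocked, rep_$offset_timelocked - 0.1)

  td <- tidy(rep_)
  expect_equal(td$onset_timelocked_ms, 1000 * rep_$onset_timelocked)
  expect_equal(nrow(td), 1)

  # the sensory weight transiently exceeds baseline after the window
  expect_gt(rep_$enhancement_gain, rep_$baseline_gain)
})

test_that("no signal-dependent noise, no suppression", {
  cfg <- sacc_config(alpha = 0)
  traj <- run_closed_loop(make_saccade_task(20, cfg), cfg)
  expect_gt(nrow(detect_saccades(traj)), 0) # the saccade itself still happens
  rep_ <- suppression_window(traj)
  expect_false(rep_$suppressed)
  base <- mean(dplyr::filter(traj, time >= 0.25, time < 0.30)$k_pos)
  expect_lt(1 - min(traj$k_pos) / base, 1e-6)
})

test_that("suppression deepens with amplitude while its timing is preserved", {
  tab <- amplitude_scaling(c(5, 10, 20, 30))
  expect_true(all(diff(tab$relative_drop) > 0))
  expect_lt(diff(range(tab$onset_ms)), 10 + 1e-9)
  expect_lt(diff(range(tab$offset_ms)), 10 + 1e-9)

  # control-noise variance is quadratic in u, so peak Vt grows supra-linearly
  expect_gt(tab$peak_v_pos[3] / tab$peak_v_pos[2], 2)
  expect_gt(tab$peak_v_pos[4] / tab$peak_v_pos[1], 30 / 5)

  # determinism: repeated amplitudes give identical rows
  tab2 <- amplitude_scaling(c(20, 20))
  expect_identical(tab2[1, -1], tab2[2, -1])
})

test_that("catch-up saccades suppress; smooth pursuit initiation does not", {
  res <- pursuit_contrast(20)
  cu <- dplyr::filter(res, variant == "catch_up")
  sm <- dplyr::filter(res, variant == "smooth")
  expect_gte(cu$n_saccades, 1)
  expect_true(cu$suppressed)
  expect_gt(cu$relative_drop, 0.01)
  expect_equal(sm$n_saccades, 0)
  expect_false(sm$suppressed)
  expect_equal(sm$relative_drop, 0)
  expect_lt(cu$terminal_error, 0.5)
  expect_lt(sm$terminal_error, 0.5)

  null <- pursuit_contrast(0, p_jump = 0)
  expect_equal(null$n_saccades, c(0, 0))
  expect_false(any(null$suppressed))
})

test_that("Monte-Carlo z-scores shrink like one over root n", {
  # against a deliberately mismatched analytic covariance (additive noise in
  # the rollouts but not in the reference), |z| grows ~ sqrt(n)
  z1 <- mc_covariance_oracle(rep(0, 25), n_rollouts = 1000, seed = 8,
                             include_additive = TRUE)$max_abs_z
  z4 <- mc_covariance_oracle(rep(0, 25), n_rollouts = 4000, seed = 8,
                             include_additive = TRUE)$max_abs_z
  expect_gt(z4 / z1, 1.4)
  expect_lt(z4 / z1, 2.8)
})
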