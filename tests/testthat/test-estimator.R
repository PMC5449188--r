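test_that("propagator is the matrix exponential with its semigroup identities", {
  cfg <- default_config()
  pl <- build_plant(cfg)
  m <- default_model(cfg)
  expect_equal(propagator(0, pl), diag(4))
  expect_equal(propagator(2 * cfg$dt, pl),
               propagator(cfg$dt, pl) %*% propagator(cfg$dt, pl),
               tolerance = 1e-10)
  expect_equal(propagator(cfg$dt, pl), m$Ad, tolerance = 1e-12)
  expect_error(propagator(-0.1, pl), "non-negative")
})

test_that("extrapolation inverts the deterministic dynamics exactly", {
  cfg <- default_config()
  m <- default_model(cfg)
  L <- m$L

  # random control schedule, noise-free rollout: reconstruction is exact
  set.seed(11)
  u <- rnorm(L + 10, sd = 20)
  x <- c(3, 0, 3, 0)
  hist <- matrix(NA_real_, 4, length(u) + 1)
  hist[, 1] <- x
  for (t in seq_along(u)) {
    x <- step_dynamics(x, u[t], m)
    hist[, t + 1] <- x
  }
  y <- hist[, ncol(hist) - L] # state L steps back, no sensory noise
  u_buf <- u[(length(u) - L + 1):length(u)]
  xex <- extrapolate_feedback(y, u_buf, m)
  expect_equal(xex, hist[, ncol(hist)], tolerance = 1e-12)

  # zero control reduces to pure propagation of the delayed sample
  y2 <- c(1, 2, 3, 4)
  expect_equal(extrapolate_feedback(y2, rep(0, L), m),
               as.numeric(m$ML %*% y2))

  # constant command at equilibrium is a fixed point
  expect_equal(extrapolate_feedback(c(8, 0, 8, 0), rep(8, L), m),
               c(8, 0, 8, 0), tolerance = 1e-12)

  expect_error(extrapolate_feedback(y2, rep(0, L - 1), m), "exactly L")
})

test_that("extrapolation covariance: sensory term, quadratic control term, copy", {
  cfg <- default_config()
  m <- default_model(cfg)
  L <- m$L

  V0 <- extrapolation_covariance(rep(0, L), m, copy = FALSE)
  expect_equal(V0, m$ML %*% m$Sigma_sigma %*% t(m$ML), tolerance = 1e-14)

  set.seed(5)
  u <- rnorm(L, sd = 15)
  V1 <- extrapolation_covariance(u, m, copy = FALSE)
  V2 <- extrapolation_covariance(2 * u, m, copy = FALSE)
  expect_equal(V2 - V0, 4 * (V1 - V0), tolerance = 1e-10)

  # the copy adds exactly the eye-block control contribution to the target block
  Vc <- extrapolation_covariance(u, m, copy = TRUE)
  expect_equal(Vc[3:4, 3:4] - V1[3:4, 3:4], V1[1:2, 1:2] - V0[1:2, 1:2],
               tolerance = 1e-12)
  expect_equal(Vc[1:2, 1:2], V1[1:2, 1:2]) # eye block untouched
  expect_symmetric_psd(Vc)
})

test_that("control-magnitude monotonicity: larger commands give PSD-larger Vt", {
  m <- default_model()
  set.seed(21)
  for (i in 1:8) {
    u <- rnorm(m$L, sd = 10)
    grow <- u * (1 + runif(m$L))
    D <- extrapolation_covariance(grow, m) - extrapolation_covariance(u, m)
    expect_symmetric_psd(D, tol = 1e-9)
  }
})

test_that("Monte-Carlo rollouts confirm the analytic extrapolation covariance", {
  cfg <- default_config()
  res <- mc_covariance_oracle(rep(20, 30), n_rollouts = 4000, seed = 3,
                              config = cfg)
  expect_lt(res$max_abs_z, 4)

  # component isolation: alpha = 0 leaves the pure sensory term
  cfg0 <- sacc_config(alpha = 0)
  res0 <- mc_covariance_oracle(rep(20, 30), n_rollouts = 4000, seed = 4,
                               config = cfg0)
  m0 <- default_model(cfg0)
  expect_equal(res0$V_analytic, m0$ML %*% m0$Sigma_sigma %*% t(m0$ML),
               tolerance = 1e-14)
  expect_lt(res0$max_abs_z, 4)
})

test_that("Kalman gain limits: balanced weighting and vanishing gain", {
  cfg <- default_config()
  m <- default_model(cfg)

  # force prediction covariance equal to the measurement covariance: K = I/2
  V <- extrapolation_covariance(rep(3, m$L), m)
  m2 <- m
  m2$Sigma_xi_est <- V
  fs <- list(x_hat = numeric(4), P = matrix(0, 4, 4))
  out <- kalman_step(fs, 0, list(x = rep(1, 4), V = V), m2)
  expect_equal(out$K, diag(4) / 2, tolerance = 1e-10)

  # infinite measurement noise: feedback ignored
  out2 <- kalman_step(fs, 0, list(x = rep(1, 4), V = 1e12 * diag(4)), m2)
  expect_lt(max(abs(out2$K)), 1e-9)
  expect_equal(out2$x_hat, out2$x_prior, tolerance = 1e-9)
})

test_that("without signal-dependent noise the filter is stationary", {
  cfg <- sacc_config(alpha = 0)
  m <- default_model(cfg)
  ss <- steady_state_filter(10, m)
  # one more predict/update cycle leaves the gain unchanged
  fs <- list(x_hat = c(10, 0, 10, 0), P = ss$P)
  out <- kalman_step(fs, 10, list(x = c(10, 0, 10, 0), V = ss$V), m)
  expect_equal(out$K, ss$K, tolerance = 1e-8)
  expect_symmetric_psd(ss$P)
  expect_true(all(diag(ss$K) >= 0 & diag(ss$K) <= 1))
})

test_that("both innovation modes agree closely at the default step size", {
  cfg_p <- sacc_config()
  cfg_l <- sacc_config(innovation_mode = "posterior_lagged")
  t1 <- run_closed_loop(make_saccade_task(20, cfg_p), cfg_p)
  t2 <- run_closed_loop(make_saccade_task(20, cfg_l), cfg_l)
  expect_equal(t2$eye_pos, t1$eye_pos, tolerance = 5e-3)
  expect_equal(t2$k_pos, t1$k_pos, tolerance = 5e-2)
  expect_false(identical(t1$eye_pos_hat, t2$eye_pos_hat))
})
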