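test_that("continuous plant matches the second-order model with augmented target", {
  cfg <- default_config()
  pl <- build_plant(cfg)
  # -1/(tau1 tau2) and -(tau1+tau2)/(tau1 tau2) at tau1 = 0.224, tau2 = 0.013
  expect_equal(pl$A[2, 1], -343.4065934, tolerance = 1e-9)
  expect_equal(pl$A[2, 2], -81.38736264, tolerance = 1e-9)
  expect_equal(pl$B[2, 1], 343.4065934, tolerance = 1e-9)
  expect_equal(pl$A[1, ], c(0, 1, 0, 0))

  # target block: constant velocity, no control authority
  expect_equal(pl$A[3, ], c(0, 0, 0, 1))
  expect_equal(pl$A[4, ], c(0, 0, 0, 0))
  expect_equal(pl$B[3:4, 1], c(0, 0))

  unit <- build_plant(sacc_config(tau1 = 1, tau2 = 1))
  expect_equal(unit$A[2, 1:2], c(-1, -2))
  expect_equal(unit$B[2, 1], 1)

  expect_error(sacc_config(tau1 = -0.2), "positive")
})

test_that("discretization is exact: zero drift, equilibrium, and semigroup", {
  cfg <- default_config()

  # A = 0 gives Ad = I, Bd = dt * B
  pl0 <- structure(list(A = matrix(0, 4, 4), B = matrix(1:4, 4, 1)),
                   class = "sacc_plant")
  m0 <- discretize(pl0, cfg)
  expect_equal(m0$Ad, diag(4))
  expect_equal(m0$Bd, cfg$dt * pl0$B)

  # the equilibrium family x1 = u, x2 = 0 is preserved by the exact step
  m <- default_model(cfg)
  for (c0 in c(-7, 1, 20)) {
    xeq <- c(c0, 0, c0, 0)
    expect_equal(as.numeric(m$Ad %*% xeq + m$Bd * c0), xeq, tolerance = 1e-12)
  }

  # semigroup: two half-steps equal one full step
  half <- sacc_config(dt = cfg$dt / 2, delta_t = cfg$delta_t)
  mh <- discretize(build_plant(half), half)
  expect_equal(mh$Ad %*% mh$Ad, m$Ad, tolerance = 1e-9)
  expect_equal(as.numeric(mh$Ad %*% mh$Bd + mh$Bd), as.numeric(m$Bd),
               tolerance = 1e-9)
})

test_that("discrete model noise structure and spectrum are as constructed", {
  m <- default_model()
  expect_equal(m$Sigma_xi, 1e-3 * m$Bd %*% t(m$Bd))
  expect_symmetric_psd(m$Sigma_xi)
  expect_equal(as.integer(Matrix::rankMatrix(m$Sigma_xi)), 1L)
  expect_equal(m$Sigma_sigma, 1e-6 * diag(4))
  expect_equal(m$alpha_prime, 0.08 / sqrt(0.005))

  # eye block strictly stable, target block on the unit circle
  ev <- sort(abs(eigen(m$Ad, only.values = TRUE)$values))
  expect_lt(ev[2], 1)
  expect_equal(ev[3:4], c(1, 1), tolerance = 1e-12)
})

test_that("stochastic step has the advertised mean and covariance", {
  cfg <- default_config()
  m <- default_model(cfg)

  # deterministic step at equilibrium leaves the state unchanged
  x <- c(5, 0, 5, 0)
  expect_equal(step_dynamics(x, 5, m), x, tolerance = 1e-12)

  # additive noise alone reproduces Sigma_xi (vectorized rank-1 draws)
  set.seed(42)
  n <- 40000
  xi <- as.numeric(sqrt(cfg$xi_scale) * m$Bd) %o% rnorm(n)
  emp <- cov(t(xi))
  se <- sqrt((diag(m$Sigma_xi) %o% diag(m$Sigma_xi) + m$Sigma_xi^2) / (n - 1))
  # entries with zero target rows have zero SE; compare the eye block
  expect_lt(max(abs(emp[1:2, 1:2] - m$Sigma_xi[1:2, 1:2]) / se[1:2, 1:2]), 4)

  # multiplicative noise alone gives alpha^2 u^2 Bd Bd'
  u <- 13
  set.seed(43)
  dev <- vapply(rnorm(n), function(e) {
    step_dynamics(c(0, 0, 0, 0), u, m, eps = e) - as.numeric(m$Bd * u)
  }, numeric(4))
  emp2 <- cov(t(dev))
  target <- cfg$alpha^2 * u^2 * m$G0
  se2 <- sqrt((diag(target) %o% diag(target) + target^2) / (n - 1))
  expect_lt(max(abs(emp2[1:2, 1:2] - target[1:2, 1:2]) / se2[1:2, 1:2]), 4)
})

test_that("observation returns the delayed state plus sensory noise", {
  cfg <- default_config()
  m <- default_model(cfg)
  states <- matrix(rnorm(4 * 30), 30, 4)

  ob <- observe(states, step = 25, m)
  expect_equal(ob$y, states[5, ])
  expect_equal(ob$stamped_step, 5)
  expect_error(observe(states, step = 10, m), "history")

  set.seed(7)
  n <- 30000
  noise <- vapply(seq_len(n), function(i) {
    observe(states, 25, m, noise = sqrt(cfg$sigma_scale) * rnorm(4))$y - states[5, ]
  }, numeric(4))
  emp <- cov(t(noise))
  expect_equal(diag(emp), rep(cfg$sigma_scale, 4), tolerance = 0.05)
  expect_lt(max(abs(emp[upper.tri(emp)])), 4 * cfg$sigma_scale / sqrt(n) * 2)
})
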