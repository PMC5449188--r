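#' Build the augmented continuous-time oculomotor plant
#'
#' The eye is modeled as a second-order low-pass filter driven by the motor
#' command `u`: eye acceleration obeys
#' `tau1 * tau2 * x2' = -x1 - (tau1 + tau2) * x2 + u`, so at equilibrium the
#' eye angle equals the command (`x1 = u`, `x2 = 0`). The plant is augmented
#' with the target position and velocity as a constant-velocity block with no
#' control authority, giving the fixed state ordering
#' (eye position, eye velocity, target position, target velocity), in degrees
#' and deg/s.
#'
#' @param config A [sacc_config()].
#' @return An object of class `sacc_plant` with elements `A` (4x4 drift
#'   matrix) and `B` (4x1 input matrix).
#' @examples
#' pl <- build_plant(sacc_config())
#' pl$A[2, 1] # -1 / (tau1 * tau2)
#' @export
build_plant <- function(config) {
  stopifnot(inherits(config, "sacc_config"))
  t1 <- config$tau1
  t2 <- config$tau2
  A <- matrix(0, 4, 4)
  A[1, 2] <- 1
  A[2, 1] <- -1 / (t1 * t2)
  A[2, 2] <- -(t1 + t2) / (t1 * t2)
  A[3, 4] <- 1 # target: constant velocity, no control authority
  B <- matrix(c(0, 1 / (t1 * t2), 0, 0), 4, 1)
  structure(list(A = A, B = B, config = config), class = "sacc_plant")
}

#' State propagator `M(t) = exp(t A)`
#'
#' @param t Propagation duration in seconds; must be non-negative.
#' @param plant A [build_plant()] result.
#' @return The 4x4 matrix exponential of `t * A`.
#' @export
propagator <- function(t, plant) {
  stopifnot(inherits(plant, "sacc_plant"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("`t` must be a single non-negative duration in seconds", call. = FALSE)
  }
  if (t == 0) return(diag(4))
  as.matrix(Matrix::expm(t * plant$A))
}

#' Discretize the plant and assemble the noise model
#'
#' Zero-order-hold discretization at step `dt`:
#' `Ad = exp(dt * A)` and `Bd = (integral_0^dt exp(s A) ds) B`, the integral
#' evaluated exactly through the exponential of the augmented block matrix
#' `[[A, B], [0, 0]]`. Noise covariances follow the configured scales:
#' `Sigma_xi = xi_scale * Bd Bd'` (additive process noise, rank 1) and
#' `Sigma_sigma = sigma_scale * I` (sensory noise).
#'
#' The returned model also carries the quantities the estimator reuses every
#' step: the powers `Ad^k` up to the delay length `L`, the propagated input
#' columns `Ad^k Bd`, the delayed sensory covariance
#' `M(delta_t) Sigma_sigma M(delta_t)'`, and the estimator-side process
#' covariance (with the eye block mirrored onto the target block when
#' `target_noise_copy` is set).
#'
#' @param plant A [build_plant()] result.
#' @param config A [sacc_config()]; defaults to the one stored in `plant`.
#' @return An object of class `sacc_model`.
#' @examples
#' m <- discretize(build_plant(sacc_config()))
#' Matrix::rankMatrix(m$Sigma_xi) # 1
#' @export
discretize <- function(plant, config = plant$config) {
  stopifnot(inherits(plant, "sacc_plant"), inherits(config, "sacc_config"))
  dt <- config$dt
  aug <- rbind(cbind(plant$A, plant$B), matrix(0, 1, 5))
  E <- as.matrix(Matrix::expm(dt * aug))
  Ad <- E[1:4, 1:4]
  Bd <- E[1:4, 5, drop = FALSE]
  G0 <- Bd %*% t(Bd)
  L <- delay_steps(config)

  M_pow <- vector("list", L + 1L)
  M_pow[[1L]] <- diag(4)
  for (k in seq_len(L)) M_pow[[k + 1L]] <- M_pow[[k]] %*% Ad
  # column k+1 holds Ad^k Bd, k = 0..L-1
  mkb <- vapply(0:(L - 1L), function(k) as.numeric(M_pow[[k + 1L]] %*% Bd),
                numeric(4))
  ML <- M_pow[[L + 1L]]
  Sigma_sigma <- config$sigma_scale * diag(4)
  Sigma_xi <- config$xi_scale * G0
  Sigma_xi_est <- if (config$target_noise_copy) copy_eye_block(Sigma_xi) else Sigma_xi

  structure(list(
    Ad = Ad, Bd = Bd, G0 = G0,
    Sigma_xi = Sigma_xi, Sigma_xi_est = Sigma_xi_est,
    Sigma_sigma = Sigma_sigma,
    alpha = config$alpha,
    alpha_prime = config$alpha / sqrt(dt),
    dt = dt, delta_t = config$delta_t, L = L,
    M_pow = M_pow, mkb = mkb, ML = ML,
    V_sens = ML %*% Sigma_sigma %*% t(ML),
    config = config, plant = plant
  ), class = "sacc_model")
}

# mirror the eye 2x2 block onto the target 2x2 diagonal block
copy_eye_block <- function(M) {
  M[3:4, 3:4] <- M[3:4, 3:4] + M[1:2, 1:2]
  M
}

#' Advance the true stochastic dynamics by one step
#'
#' Computes `Ad x + Bd u + alpha * eps * Bd u + xi`: the deterministic step
#' plus multiplicative control noise (a single scalar standard-normal draw
#' `eps` scaling the command along `Bd`) plus additive process noise `xi`.
#' With all draws zero this is the exact noise-free mean step.
#'
#' @param x State 4-vector (eye pos, eye vel, target pos, target vel).
#' @param u Motor command (scalar).
#' @param model A [discretize()] result.
#' @param eps Standard-normal scalar draw for the multiplicative noise
#'   (default 0).
#' @param xi Additive process noise 4-vector, distributed `N(0, Sigma_xi)`
#'   when simulating (default zero).
#' @return The state at the next step as a plain numeric 4-vector.
#' @export
step_dynamics <- function(x, u, model, eps = 0, xi = numeric(4)) {
  stopifnot(inherits(model, "sacc_model"))
  if (!all(is.finite(x)) || !is.finite(u)) {
    stop("non-finite state or control passed to step_dynamics", call. = FALSE)
  }
  as.numeric(model$Ad %*% x + model$Bd * (u * (1 + model$alpha * eps)) + xi)
}

# draw xi ~ N(0, xi_scale * Bd Bd') using the rank-1 structure
draw_xi <- function(model, z = stats::rnorm(1)) {
  as.numeric(sqrt(model$config$xi_scale) * model$Bd) * z
}

#' Delayed, noisy observation of the state
#'
#' Returns `y(t) = x(t - delta_t) + sigma`, looking the delayed state up in a
#' recorded state history. The simulation engine pre-pads its history with
#' the initial fixation state, so the delayed sample is defined from the
#' first step onwards.
#'
#' @param states Numeric matrix of recorded states, one row per step
#'   (row `i` is the state at step `i`).
#' @param step Integer step index at which the observation is formed.
#' @param model A [discretize()] result.
#' @param noise Sensory noise 4-vector (`N(0, Sigma_sigma)` when simulating;
#'   default zero).
#' @return A list with the observed 4-vector `y` and `stamped_step`
#'   (`step - L`, the time the observation reflects).
#' @export
observe <- function(states, step, model, noise = numeric(4)) {
  stopifnot(inherits(model, "sacc_model"))
  i <- step - model$L
  if (i < 1L || i > nrow(states)) {
    stop("internal error: state history does not reach back to step ", i,
         call. = FALSE)
  }
  list(y = as.numeric(states[i, ]) + noise, stamped_step = i)
}
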