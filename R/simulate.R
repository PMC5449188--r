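#' Run the closed control loop and record the trajectory
#'
#' Wires plant, estimator and controller together with the sensorimotor
#' delay buffer. Each step: form the delayed observation, extrapolate it to
#' the present through the stored commands, run the Kalman predict/update,
#' emit the feedback command, and advance the true stochastic dynamics. The
#' delay buffer and the filter are warm-started in fixation steady state
#' (the history is pre-padded with the initial fixation state and its
#' holding command, and the filter covariance is the converged fixation
#' solution), so the recorded baseline is stationary from the first step.
#'
#' With `seed = NULL` (the default) every noise realization is zero while
#' the estimator still uses the full noise covariances: this is the
#' deterministic mean rollout that reproduces the package's reference
#' figures. With an integer seed the multiplicative, additive and sensory
#' noises are drawn.
#'
#' Scheduled target jumps are instantaneous edits of the true target state.
#' Jumps marked `known` (the saccade-task target switch) are applied to the
#' estimator and its delayed-state history as well -- a pre-planned goal --
#' whereas surprise jumps (pursuit) reach the estimator only through the
#' delayed feedback.
#'
#' @param task A `sacc_task` from [make_saccade_task()] or
#'   [make_pursuit_task()].
#' @param config A [sacc_config()].
#' @param seed Integer seed for the noise draws, or `NULL` for the
#'   noise-free mean rollout.
#' @param keep_matrices If `TRUE`, attach the full per-step gain, posterior
#'   and extrapolation covariance matrices as attributes `K_hist`, `P_hist`,
#'   `V_hist` (4 x 4 x (T+1) arrays).
#' @return A `sacc_trajectory`: a tibble with one row per step carrying the
#'   true state, the estimate, the one-step prediction, the command `u`, the
#'   per-step control-noise variance, the position entry and trace of the
#'   extrapolation covariance, the diagonal Kalman gains (`k_pos` is the
#'   weight of position feedback), and the posterior variances. The resolved
#'   config, task, model and Riccati solution ride along as attributes.
#' @examples
#' cfg <- sacc_config()
#' traj <- run_closed_loop(make_saccade_task(20, cfg), cfg)
#' detect_saccades(traj)
#' @export
run_closed_loop <- function(task, config = sacc_config(), seed = NULL,
                            keep_matrices = FALSE) {
  stopifnot(inherits(task, "sacc_task"), inherits(config, "sacc_config"))
  model <- discretize(build_plant(config), config)
  costs <- build_cost_schedule(task, config)
  sol <- riccati_backward(model, costs)
  L <- model$L
  dt <- model$dt
  Tn <- task$n_steps
  n <- Tn + 1L

  noisy <- !is.null(seed)
  if (noisy) {
    set.seed(seed)
    eps_draws <- stats::rnorm(n)
    xi_draws <- stats::rnorm(n)
    sg_draws <- matrix(stats::rnorm(4L * n), 4L, n)
  }

  # fixation steady state at the first target: x1 = u = target, x2 = 0
  x <- task$x0
  u_hold <- task$x0[1]
  ss <- steady_state_filter(u_hold, model)
  fs <- list(x_hat = x, P = ss$P)
  u_prev <- u_hold
  ubuf <- rep(u_hold, L)
  xbuf <- matrix(x, 4L, L) # states at steps t-L .. t-1, oldest first

  jumps <- task$jumps
  jump_step <- if (nrow(jumps)) as.integer(round(jumps$time / dt)) + 1L else integer(0)

  rec <- matrix(NA_real_, n, 25L)
  colnames(rec) <- c(
    "time", "eye_pos", "eye_vel", "target_pos", "target_vel",
    "eye_pos_hat", "eye_vel_hat", "target_pos_hat", "target_vel_hat",
    "eye_pos_prior", "eye_vel_prior", "target_pos_prior", "target_vel_prior",
    "u", "control_var", "v_pos", "v_trace",
    "k_pos", "k_vel", "k_tpos", "k_tvel",
    "p_pos", "p_vel", "p_tpos", "p_tvel"
  )
  if (keep_matrices) {
    K_hist <- array(NA_real_, c(4, 4, n))
    P_hist <- array(NA_real_, c(4, 4, n))
    V_hist <- array(NA_real_, c(4, 4, n))
  }

  for (t in seq_len(n)) {
    hit <- which(jump_step == t)
    for (j in hit) {
      x[3] <- x[3] + jumps$d_pos[j]
      x[4] <- x[4] + jumps$d_vel[j]
      if (jumps$known[j]) {
        fs$x_hat[3] <- fs$x_hat[3] + jumps$d_pos[j]
        fs$x_hat[4] <- fs$x_hat[4] + jumps$d_vel[j]
        xbuf[3, ] <- xbuf[3, ] + jumps$d_pos[j]
        xbuf[4, ] <- xbuf[4, ] + jumps$d_vel[j]
      }
    }

    sigma <- if (noisy) sqrt(config$sigma_scale) * sg_draws[, t] else numeric(4)
    y <- xbuf[, 1] + sigma
    extrap <- list(
      x = extrapolate_feedback(y, ubuf, model),
      V = extrapolation_covariance(ubuf, model)
    )
    fs <- kalman_step(fs, u_prev, extrap, model)
    u <- control_law(fs$x_hat, min(t, Tn), sol)

    if (!all(is.finite(fs$x_hat)) || !is.finite(u)) {
      stop("numerical divergence at step ", t, " (t = ", (t - 1) * dt,
           " s): non-finite estimate or command", call. = FALSE)
    }

    rec[t, ] <- c(
      (t - 1L) * dt, x, fs$x_hat, fs$x_prior, u,
      model$alpha^2 * u^2 * model$G0[2, 2],
      extrap$V[1, 1], sum(diag(extrap$V)),
      fs$K[1, 1], fs$K[2, 2], fs$K[3, 3], fs$K[4, 4],
      fs$P[1, 1], fs$P[2, 2], fs$P[3, 3], fs$P[4, 4]
    )
    if (keep_matrices) {
      K_hist[, , t] <- fs$K
      P_hist[, , t] <- fs$P
      V_hist[, , t] <- extrap$V
    }

    eps <- if (noisy) eps_draws[t] else 0
    xi <- if (noisy) draw_xi(model, xi_draws[t]) else numeric(4)
    xbuf <- cbind(xbuf[, -1, drop = FALSE], x)
    x <- step_dynamics(x, u, model, eps = eps, xi = xi)
    ubuf <- c(ubuf[-1], u)
    u_prev <- u
  }

  out <- tibble::as_tibble(as.data.frame(rec))
  attr(out, "config") <- config
  attr(out, "task") <- task
  attr(out, "model") <- model
  attr(out, "riccati") <- sol
  attr(out, "seed") <- seed
  if (keep_matrices) {
    attr(out, "K_hist") <- K_hist
    attr(out, "P_hist") <- P_hist
    attr(out, "V_hist") <- V_hist
  }
  class(out) <- c("sacc_trajectory", class(out))
  out
}

traj_config <- function(traj) {
  cfg <- attr(traj, "config")
  if (is.null(cfg)) {
    stop("trajectory has no attached config (was it read from a bare CSV?); ",
         "pass `config` explicitly", call. = FALSE)
  }
  cfg
}
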