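#' Build the time-varying quadratic cost schedule for a task
#'
#' During fixation and pursuit epochs the state cost penalizes the squared
#' eye-minus-target position error, `w_p * (x1 - x3)^2`, encoded through the
#' augmented target state as `Q = w_p * c c'` with `c = (1, 0, -1, 0)` (plus
#' an optional `w_v` velocity-error term on `(0, 1, 0, -1)`). During movement
#' windows the state is free: `Q = 0`. The motor command always costs
#' `R u^2`. The terminal value matrix is the final-epoch cost scaled by
#' `terminal_scale`, standing in for fixation continuing past the horizon.
#'
#' @param task A `sacc_task`.
#' @param config A [sacc_config()].
#' @return A `sacc_costs` object: `Q` (4 x 4 x (T+1) array), scalar `R`,
#'   horizon `T` in steps, and the terminal matrix `S_T`.
#' @export
build_cost_schedule <- function(task, config = sacc_config()) {
  stopifnot(inherits(task, "sacc_task"), inherits(config, "sacc_config"))
  kinds <- epoch_kind_by_step(task, config)
  Tn <- task$n_steps
  stopifnot(length(kinds) == Tn + 1L)
  cp <- c(1, 0, -1, 0)
  cv <- c(0, 1, 0, -1)
  Q_fix <- config$w_p * outer(cp, cp) + config$w_v * outer(cv, cv)
  Q <- array(0, c(4, 4, Tn + 1L))
  for (t in seq_len(Tn + 1L)) {
    if (kinds[t] != "movement") Q[, , t] <- Q_fix
  }
  structure(list(
    Q = Q, R = config$r_cost, T = Tn,
    S_T = config$terminal_scale * Q[, , Tn + 1L]
  ), class = "sacc_costs")
}

#' Backward Riccati recursion for the finite-horizon LQR
#'
#' Solves `S_T = terminal cost`; for `t = T-1 .. 0`:
#' `L_t = (R + Bd' S_{t+1} Bd)^-1 Bd' S_{t+1} Ad` and
#' `S_t = Q_t + Ad' S_{t+1} (Ad - Bd L_t)`, each `S_t` symmetrized. The
#' controller is computed on the noise-free problem -- the multiplicative
#' motor noise is deliberately ignored here and handled by the estimator, so
#' controller and estimator are not jointly optimized.
#'
#' @param model A [discretize()] result.
#' @param costs A [build_cost_schedule()] result.
#' @return A `sacc_riccati` object with the value matrices `S`
#'   (4 x 4 x (T+1)) and feedback gain rows `L` (T x 4).
#' @export
riccati_backward <- function(model, costs) {
  stopifnot(inherits(model, "sacc_model"), inherits(costs, "sacc_costs"))
  Ad <- model$Ad
  Bd <- model$Bd
  Tn <- costs$T
  S <- array(0, c(4, 4, Tn + 1L))
  Lg <- matrix(0, Tn, 4)
  S[, , Tn + 1L] <- costs$S_T
  St1 <- costs$S_T
  for (t in Tn:1) {
    g <- as.numeric(costs$R + t(Bd) %*% St1 %*% Bd) # scalar, > 0 since R > 0
    Lt <- (t(Bd) %*% St1 %*% Ad) / g
    St <- costs$Q[, , t] + t(Ad) %*% St1 %*% (Ad - Bd %*% Lt)
    St <- (St + t(St)) / 2
    S[, , t] <- St
    Lg[t, ] <- Lt
    St1 <- St
  }
  structure(list(S = S, L = Lg, T = Tn), class = "sacc_riccati")
}

#' Evaluate the feedback control law
#'
#' `u(t) = -L_t x_hat`: the command is a linear feedback on the current
#' state estimate, using the precomputed time-varying Riccati gain.
#'
#' @param x_hat State estimate 4-vector.
#' @param t Step index, 1-based, `1 <= t <= T`.
#' @param sol A [riccati_backward()] result.
#' @return The scalar motor command.
#' @export
control_law <- function(x_hat, t, sol) {
  stopifnot(inherits(sol, "sacc_riccati"))
  if (t < 1L || t > sol$T) {
    stop("step ", t, " outside the control horizon [1, ", sol$T, "]",
         call. = FALSE)
  }
  -as.numeric(sol$L[t, ] %*% x_hat)
}

#' Export a Riccati solution as a tidy table
#'
#' @param x A `sacc_riccati` object.
#' @param ... Unused.
#' @return A tibble with one row per step: the four feedback gains and the
#'   diagonal of the value matrix.
#' @export
tidy.sacc_riccati <- function(x, ...) {
  tibble::tibble(
    step = seq_len(x$T),
    l_eye_pos = x$L[, 1], l_eye_vel = x$L[, 2],
    l_target_pos = x$L[, 3], l_target_vel = x$L[, 4],
    s_eye_pos = x$S[1, 1, seq_len(x$T)],
    s_eye_vel = x$S[2, 2, seq_len(x$T)]
  )
}
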