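#' Extrapolate delayed sensory feedback to the present
#'
#' The retinal signal available at time `t` reflects the state at
#' `t - delta_t`. The estimator projects it forward using the stored motor
#' commands: `x(t|y) = Ad^L y + sum_k Ad^(L-k) Bd u_k`, the discrete
#' convolution of the delayed observation with the control history, matched
#' exactly to the piecewise-constant control used by the simulator. In the
#' absence of noise this inverts the deterministic dynamics and recovers the
#' true present state to machine precision.
#'
#' @param y Observed (delayed) state 4-vector.
#' @param u_hist Control history over the delay interval: numeric vector of
#'   length `L`, oldest command first.
#' @param model A [discretize()] result.
#' @return The extrapolated present-state estimate, a numeric 4-vector.
#' @export
extrapolate_feedback <- function(y, u_hist, model) {
  stopifnot(inherits(model, "sacc_model"))
  if (length(u_hist) != model$L) {
    stop("`u_hist` must hold exactly L = ", model$L, " commands", call. = FALSE)
  }
  # u_k (oldest first) is propagated by Ad^(L-k): reverse aligns with mkb cols
  as.numeric(model$ML %*% y + model$mkb %*% rev(u_hist))
}

#' Covariance of the extrapolation error
#'
#' The extrapolation error is Gaussian with covariance
#' `Vt = M(delta_t) Sigma_sigma M(delta_t)' +
#'       sum_k alpha^2 u_k^2 Ad^(L-k) Bd Bd' (Ad^(L-k))'`:
#' the delayed sensory noise propagated to the present, plus every
#' signal-dependent noise pulse injected during the delay interval,
#' propagated from its injection time. `Vt` therefore grows with the square
#' of the buffered commands -- the mechanism behind perisaccadic suppression.
#' When `copy` is set (the config default) the eye-block control contribution
#' is mirrored onto the target block, expressing that feedback about the
#' target shares the uncertainty about the eye.
#'
#' @inheritParams extrapolate_feedback
#' @param copy Mirror the control-dependent eye block onto the target block;
#'   defaults to the `copy_target_vt` config flag.
#' @return A symmetric positive semi-definite 4x4 matrix.
#' @export
extrapolation_covariance <- function(u_hist, model,
                                     copy = model$config$copy_target_vt) {
  stopifnot(inherits(model, "sacc_model"))
  if (length(u_hist) != model$L) {
    stop("`u_hist` must hold exactly L = ", model$L, " commands", call. = FALSE)
  }
  w <- model$alpha^2 * rev(u_hist)^2
  Vc <- (model$mkb * rep(w, each = 4L)) %*% t(model$mkb)
  if (copy) Vc <- copy_eye_block(Vc) # control-dependent part only
  V <- model$V_sens + Vc
  (V + t(V)) / 2
}

#' One predict/update cycle of the adaptive Kalman filter
#'
#' Starting from the posterior at step `t`, predicts one step ahead with the
#' forward model (`x_pred = Ad x_hat + Bd u`), forms the gain
#' `K = P_pred (P_pred + Vt)^-1` against the extrapolated full-state
#' pseudo-measurement, and corrects the prediction with the innovation. The
#' prediction covariance carries the additive process noise, and -- only if
#' `prior_control_noise` is configured -- the multiplicative term
#' `alpha^2 u^2 Bd Bd'`. The posterior covariance is symmetrized each step.
#'
#' Under `innovation_mode = "posterior_lagged"` the innovation is referenced
#' to the previous posterior rather than to the prediction, mirroring an
#' alternative time-indexing of the update; both modes coincide as
#' `dt -> 0`.
#'
#' @param fs Filter state: list with posterior mean `x_hat` and covariance
#'   `P` (as returned by this function or [steady_state_filter()]).
#' @param u Command applied between the previous and the current step.
#' @param extrap List with the extrapolated measurement `x` and its
#'   covariance `V` (from [extrapolate_feedback()] and
#'   [extrapolation_covariance()]).
#' @param model A [discretize()] result.
#' @return The updated filter state: `x_hat`, `P`, gain `K`, prediction
#'   `x_prior` and prediction covariance `P_prior`.
#' @export
kalman_step <- function(fs, u, extrap, model) {
  stopifnot(inherits(model, "sacc_model"))
  cfg <- model$config
  x_pred <- as.numeric(model$Ad %*% fs$x_hat + model$Bd * u)
  P_pred <- model$Ad %*% fs$P %*% t(model$Ad) + model$Sigma_xi_est
  if (cfg$prior_control_noise) {
    Qc <- cfg$alpha^2 * u^2 * model$G0
    if (cfg$target_noise_copy) Qc <- copy_eye_block(Qc)
    P_pred <- P_pred + Qc
  }
  P_pred <- (P_pred + t(P_pred)) / 2
  K <- P_pred %*% solve(P_pred + extrap$V)
  ref <- if (cfg$innovation_mode == "prior") x_pred else fs$x_hat
  x_hat <- x_pred + as.numeric(K %*% (extrap$x - ref))
  P <- (diag(4) - K) %*% P_pred
  P <- (P + t(P)) / 2
  list(x_hat = x_hat, P = P, K = K, x_prior = x_pred, P_prior = P_pred)
}

#' Steady-state filter under a constant holding command
#'
#' Iterates the covariance recursion with a constant command until the
#' prediction covariance converges. Used to warm-start simulations in
#' fixation steady state and to study the fixation baseline gain.
#'
#' @param u_hold Constant command (equals the fixated eye angle in degrees).
#' @param model A [discretize()] result.
#' @param tol Convergence tolerance on the prediction covariance.
#' @param max_iter Iteration cap; convergence failure is an error.
#' @return List with converged `P` (posterior), `P_prior`, gain `K`, and the
#'   extrapolation covariance `V` at the holding command.
#' @export
steady_state_filter <- function(u_hold, model, tol = 1e-14, max_iter = 20000L) {
  stopifnot(inherits(model, "sacc_model"))
  cfg <- model$config
  V <- extrapolation_covariance(rep(u_hold, model$L), model)
  Qc <- matrix(0, 4, 4)
  if (cfg$prior_control_noise) {
    Qc <- cfg$alpha^2 * u_hold^2 * model$G0
    if (cfg$target_noise_copy) Qc <- copy_eye_block(Qc)
  }
  P_pred <- model$Sigma_xi_est + Qc
  K <- NULL
  for (i in seq_len(max_iter)) {
    K <- P_pred %*% solve(P_pred + V)
    P <- (diag(4) - K) %*% P_pred
    P <- (P + t(P)) / 2
    P_next <- model$Ad %*% P %*% t(model$Ad) + model$Sigma_xi_est + Qc
    P_next <- (P_next + t(P_next)) / 2
    if (max(abs(P_next - P_pred)) < tol) {
      return(list(P = P, P_prior = P_next, K = K, V = V))
    }
    P_pred <- P_next
  }
  stop("steady-state filter did not converge within ", max_iter, " iterations",
       call. = FALSE)
}
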