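#' Model configuration for the oculomotor control loop
#'
#' Collects every scalar parameter of the plant, the noise model, the
#' estimator and the controller. Defaults are the values used throughout the
#' package's reference simulations: plant time constants of 224 ms and 13 ms,
#' a 5 ms discretization step, a 100 ms sensorimotor delay, signal-dependent
#' motor noise scale `alpha = 0.08`, additive process noise
#' `Sigma_xi = 1e-3 * Bd %*% t(Bd)`, sensory noise `Sigma_sigma = 1e-6 * I`,
#' and control cost `R = 0.01`.
#'
#' @param tau1,tau2 Plant time constants in seconds. The oculomotor plant is
#'   a second-order low-pass filter; `tau1` is the slow (orbital tissue) and
#'   `tau2` the fast (muscle activation) time constant.
#' @param dt Discretization step in seconds.
#' @param delta_t Sensorimotor delay in seconds. Must be an integer multiple
#'   of `dt`; the delay buffer then holds `L = delta_t / dt` commands.
#' @param alpha Scale of the multiplicative (signal-dependent) motor noise:
#'   each control pulse `u` carries noise with standard deviation
#'   `alpha * |u|` along `Bd`.
#' @param xi_scale Scale of the additive process noise covariance
#'   `Sigma_xi = xi_scale * Bd %*% t(Bd)`.
#' @param sigma_scale Scale of the sensory noise covariance
#'   `Sigma_sigma = sigma_scale * I`.
#' @param r_cost Quadratic cost weight on the motor command.
#' @param w_p Position-error cost weight during fixation and pursuit epochs.
#'   The default (20) produces 20-deg saccades of roughly 50-70 ms with a
#'   realistic agonist burst and antagonistic braking inflection; see the
#'   methods vignette for the calibration rationale.
#' @param w_v Optional velocity-error cost weight on eye-minus-target
#'   velocity (default 0: position-only cost).
#' @param terminal_scale Multiplier on the final-epoch state cost used as the
#'   terminal value matrix of the finite-horizon controller. Approximates
#'   fixation continuing beyond the simulated horizon so the gain does not
#'   relax to zero in the last few steps.
#' @param innovation_mode `"prior"` (default) corrects the one-step
#'   prediction with the innovation referenced to that same prediction (the
#'   standard Kalman recursion); `"posterior_lagged"` references the
#'   innovation to the previous posterior instead, reproducing an alternative
#'   indexing of the update equation. The two are numerically close at
#'   `dt = 5` ms.
#' @param prior_control_noise If `TRUE`, the one-step prediction covariance
#'   additionally carries the multiplicative control noise
#'   `alpha^2 u^2 Bd Bd'`. Default `FALSE`: control-dependent uncertainty is
#'   accounted for once, in the extrapolation covariance, which is what
#'   places the gain reduction at saccade onset (see vignette).
#' @param copy_target_vt If `TRUE` (default), the control-dependent eye-block
#'   contribution to the extrapolation covariance is mirrored onto the target
#'   block: there is no retinal measurement of the target independent of the
#'   eye, so uncertainty about the eye contaminates feedback about the
#'   target by the same amount.
#' @param target_noise_copy If `TRUE` (default), the estimator's process
#'   covariance likewise mirrors the eye-block additive noise onto the target
#'   block, keeping the target filter stationary (without it the target gain
#'   decays like 1/t and the model cannot generate catch-up saccades).
#'
#' @return An object of class `sacc_config`: a validated named list.
#' @examples
#' cfg <- sacc_config()
#' cfg$delta_t / cfg$dt # delay buffer length, 20 steps
#' @seealso [build_plant()], [discretize()], [run_closed_loop()]
#' @export
sacc_config <- function(tau1 = 0.224, tau2 = 0.013, dt = 0.005, delta_t = 0.100,
                        alpha = 0.08, xi_scale = 1e-3, sigma_scale = 1e-6,
                        r_cost = 0.01, w_p = 20, w_v = 0, terminal_scale = 100,
                        innovation_mode = c("prior", "posterior_lagged"),
                        prior_control_noise = FALSE,
                        copy_target_vt = TRUE,
                        target_noise_copy = TRUE) {
  innovation_mode <- match.arg(innovation_mode)
  cfg <- list(
    tau1 = tau1, tau2 = tau2, dt = dt, delta_t = delta_t, alpha = alpha,
    xi_scale = xi_scale, sigma_scale = sigma_scale, r_cost = r_cost,
    w_p = w_p, w_v = w_v, terminal_scale = terminal_scale,
    innovation_mode = innovation_mode,
    prior_control_noise = isTRUE(prior_control_noise),
    copy_target_vt = isTRUE(copy_target_vt),
    target_noise_copy = isTRUE(target_noise_copy)
  )
  class(cfg) <- "sacc_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  pos <- c("tau1", "tau2", "dt", "delta_t", "xi_scale", "sigma_scale",
           "r_cost", "terminal_scale")
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("configuration error: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  for (nm in c("alpha", "w_p", "w_v")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("configuration error: `", nm, "` must be a single non-negative number",
           call. = FALSE)
    }
  }
  L <- cfg$delta_t / cfg$dt
  if (abs(L - round(L)) > 1e-8) {
    stop("configuration error: `delta_t` (", cfg$delta_t,
         " s) must be an integer multiple of `dt` (", cfg$dt, " s)",
         call. = FALSE)
  }
  cfg
}

# delay buffer length in steps
delay_steps <- function(cfg) as.integer(round(cfg$delta_t / cfg$dt))

#' @export
print.sacc_config <- function(x, ...) {
  cat("<sacc_config>\n")
  cat(sprintf("  plant:      tau1 = %g s, tau2 = %g s\n", x$tau1, x$tau2))
  cat(sprintf("  timing:     dt = %g s, delay = %g s (L = %d steps)\n",
              x$dt, x$delta_t, delay_steps(x)))
  cat(sprintf("  noise:      alpha = %g, xi_scale = %g, sigma_scale = %g\n",
              x$alpha, x$xi_scale, x$sigma_scale))
  cat(sprintf("  cost:       R = %g, w_p = %g, w_v = %g, terminal x%g\n",
              x$r_cost, x$w_p, x$w_v, x$terminal_scale))
  cat(sprintf("  estimator:  innovation = %s, prior control noise = %s,\n",
              x$innovation_mode, x$prior_control_noise))
  cat(sprintf("              Vt target copy = %s, process target copy = %s\n",
              x$copy_target_vt, x$target_noise_copy))
  invisible(x)
}
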