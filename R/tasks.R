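#' Define a two-fixation saccade task
#'
#' Builds the canonical saccade timeline: fixation at the first target,
#' a movement window during which the state carries no cost (the eye is free
#' to move), then fixation at the second target. By default the targets are
#' symmetric about zero (`-amplitude/2` to `+amplitude/2`) so the holding
#' command -- and with it the fixation-steady sensory weight -- is identical
#' before and after the saccade; pass `from`/`to` to place the targets
#' elsewhere.
#'
#' The target switch is scheduled at the start of the movement window and is
#' marked `known`: it represents the pre-planned goal of the saccade, so it
#' is applied to the true target state and to the estimator alike. Surprise
#' target jumps (see [make_pursuit_task()]) are instead learned through the
#' delayed feedback.
#'
#' @param amplitude Saccade amplitude in degrees (nonzero sign gives
#'   direction; 0 is allowed and yields a degenerate no-saccade task).
#' @param config A [sacc_config()].
#' @param from,to Fixation targets in degrees.
#' @param fix1,movement,fix2 Epoch durations in seconds (defaults 300 ms,
#'   50 ms, 650 ms). Must be multiples of `dt`.
#' @return A `sacc_task`: epochs and jumps tibbles plus the initial state.
#' @examples
#' make_saccade_task(20, sacc_config())
#' @export
make_saccade_task <- function(amplitude, config = sacc_config(),
                              from = -amplitude / 2, to = from + amplitude,
                              fix1 = 0.300, movement = 0.050, fix2 = 0.650) {
  epochs <- tibble::tibble(
    kind = c("fixation", "movement", "fixation"),
    duration = c(fix1, movement, fix2),
    target_pos = c(from, to, to),
    target_vel = 0
  )
  jumps <- tibble::tibble(
    time = fix1, d_pos = to - from, d_vel = 0, known = TRUE
  )
  if (amplitude == 0) jumps <- jumps[0, ]
  new_task(epochs, jumps, config)
}

#' Define a pursuit task with a target velocity (and optional position) jump
#'
#' The eye fixates a stationary target; at `jump_time` the target abruptly
#' starts moving at `v_jump` deg/s, optionally displaced by `p_jump` deg at
#' the same instant. The jump is a surprise: only the true target state
#' changes, and the estimator discovers it through the delayed feedback.
#' Position error therefore accumulates at the target speed over one delay
#' (`v_jump * delta_t`, 2 deg at the defaults), and correcting it produces a
#' catch-up saccade -- unless `p_jump = -v_jump * delta_t` cancels the
#' accumulating error, in which case pursuit starts smoothly.
#'
#' @param v_jump Target velocity after the jump, deg/s.
#' @param p_jump Instantaneous target displacement at the jump, deg.
#' @param config A [sacc_config()].
#' @param duration Total simulated time in seconds.
#' @param jump_time Time of the jump in seconds.
#' @return A `sacc_task`.
#' @export
make_pursuit_task <- function(v_jump, p_jump = 0, config = sacc_config(),
                              duration = 1.0, jump_time = 0.300) {
  epochs <- tibble::tibble(
    kind = "pursuit", duration = duration, target_pos = 0, target_vel = 0
  )
  jumps <- tibble::tibble(
    time = jump_time, d_pos = p_jump, d_vel = v_jump, known = FALSE
  )
  if (v_jump == 0 && p_jump == 0) jumps <- jumps[0, ]
  new_task(epochs, jumps, config)
}

new_task <- function(epochs, jumps, config) {
  dt <- config$dt
  if (any(epochs$duration <= 0)) {
    stop("configuration error: epoch durations must be positive", call. = FALSE)
  }
  steps <- epochs$duration / dt
  if (any(abs(steps - round(steps)) > 1e-8)) {
    stop("configuration error: epoch durations must be multiples of dt = ",
         dt, " s", call. = FALSE)
  }
  horizon <- sum(epochs$duration)
  if (nrow(jumps) && any(jumps$time < 0 | jumps$time > horizon)) {
    stop("configuration error: jump times must lie within the task horizon",
         call. = FALSE)
  }
  structure(list(
    epochs = epochs, jumps = jumps,
    horizon = horizon, n_steps = as.integer(round(horizon / dt)),
    x0 = c(epochs$target_pos[1], 0, epochs$target_pos[1], epochs$target_vel[1])
  ), class = "sacc_task")
}

#' @export
print.sacc_task <- function(x, ...) {
  cat("<sacc_task> horizon", x$horizon, "s (", x$n_steps, "steps )\n")
  print(x$epochs)
  if (nrow(x$jumps)) {
    cat("jumps:\n")
    print(x$jumps)
  }
  invisible(x)
}

# per-step epoch kind over t = 0..T (length T+1); step t covers [t*dt, (t+1)*dt)
epoch_kind_by_step <- function(task, config) {
  dt <- config$dt
  bounds <- cumsum(task$epochs$duration)
  times <- seq(0, task$horizon, by = dt)
  idx <- findInterval(times + dt / 4, c(0, bounds), rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(task$epochs))
  task$epochs$kind[idx]
}
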