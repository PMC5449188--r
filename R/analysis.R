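#' Detect saccades in a trajectory
#'
#' Standard velocity-threshold detection: saccades are maximal runs where
#' the absolute eye velocity exceeds `v_threshold`, with sub-threshold gaps
#' shorter than `merge_gap` merged into one event. Amplitude is the eye
#' displacement over the run.
#'
#' @param traj A `sacc_trajectory` (or any data frame with `time`,
#'   `eye_pos`, `eye_vel` columns).
#' @param v_threshold Velocity threshold in deg/s (default 30).
#' @param merge_gap Maximum sub-threshold gap to merge, in seconds
#'   (default 10 ms).
#' @return A tibble of events: `onset`, `offset` (seconds), `duration`,
#'   `amplitude` (deg), `peak_velocity` (deg/s). Zero rows when no sample
#'   crosses threshold.
#' @export
detect_saccades <- function(traj, v_threshold = 30, merge_gap = 0.010) {
  stopifnot(all(c("time", "eye_pos", "eye_vel") %in% names(traj)))
  v <- traj$eye_vel
  if (!all(is.finite(v))) stop("non-finite velocities in trajectory", call. = FALSE)
  above <- abs(v) > v_threshold
  if (!any(above)) {
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          duration = numeric(), amplitude = numeric(),
                          peak_velocity = numeric()))
  }
  dt <- traj$time[2] - traj$time[1]
  r <- rle(above)
  # close interior sub-threshold gaps shorter than merge_gap
  n_runs <- length(r$lengths)
  interior <- which(!r$values & seq_along(r$values) > 1L &
                      seq_along(r$values) < n_runs)
  r$values[interior[r$lengths[interior] * dt < merge_gap]] <- TRUE
  above <- inverse.rle(r)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  purrr::map_dfr(keep, function(ri) {
    i0 <- starts[ri]
    i1 <- ends[ri]
    tibble::tibble(
      onset = traj$time[i0],
      offset = traj$time[i1] + dt,
      duration = traj$time[i1] + dt - traj$time[i0],
      amplitude = traj$eye_pos[i1] - traj$eye_pos[i0],
      peak_velocity = max(abs(v[i0:i1]))
    )
  })
}

#' Perisaccadic suppression window from the Kalman position weight
#'
#' Derives the suppression report: the fixation baseline of the position
#' feedback weight `k_pos` (mean over the last `baseline_window` seconds of
#' pre-movement fixation), the contiguous run around the saccade during
#' which `k_pos` falls more than `rel_tol` below baseline, and the window
#' bounds both time-locked (relative to saccade onset) and stimulus-locked
#' (shifted earlier by the sensorimotor delay: a stimulus is weighted
#' `delta_t` after it occurs, so the suppressed stimulus times are the
#' time-locked bounds minus `delta_t`).
#'
#' For pursuit-style analyses pass `reference`: a second trajectory whose
#' `k_pos` trace serves as a time-matched baseline (the gain depends on the
#' holding command, so during tracking the fair reference is a matched run
#' without the saccade, not the pre-jump fixation level).
#'
#' @param traj A `sacc_trajectory`.
#' @param saccade A one-row saccade event ([detect_saccades()] row);
#'   defaults to the first detected saccade.
#' @param rel_tol Relative drop defining the window edges (default 1%).
#' @param baseline_window Length of the baseline averaging window in
#'   seconds (default 50 ms).
#' @param reference Optional time-matched reference trajectory.
#' @param config Model configuration; defaults to the one attached to
#'   `traj`.
#' @return A `suppression_report` list: `suppressed` flag, `baseline_gain`,
#'   `min_gain`, `relative_drop`, window bounds `onset_timelocked`,
#'   `offset_timelocked`, `onset_stimlocked`, `offset_stimlocked` (seconds,
#'   relative to saccade onset), `enhancement_gain` (maximum `k_pos` in the
#'   100 ms after the window), and the saccade event. Use [generics::tidy()]
#'   for a one-row tibble in milliseconds.
#' @export
suppression_window <- function(traj, saccade = NULL, rel_tol = 0.01,
                               baseline_window = 0.050, reference = NULL,
                               config = NULL) {
  cfg <- config %||% traj_config(traj)
  dt <- cfg$dt
  if (is.null(saccade)) {
    ev <- detect_saccades(traj)
    if (nrow(ev) == 0L) {
      return(empty_suppression_report(reason = "no saccade detected"))
    }
    saccade <- ev[1, ]
  }
  onset <- saccade$onset

  base_end <- baseline_end_time(traj, cfg, onset)
  in_base <- traj$time >= base_end - baseline_window & traj$time < base_end
  if (!any(in_base)) {
    stop("no samples in the baseline window before ", base_end, " s",
         call. = FALSE)
  }
  baseline <- mean(traj$k_pos[in_base])

  ref_trace <- if (is.null(reference)) rep(baseline, nrow(traj)) else reference$k_pos
  if (length(ref_trace) != nrow(traj)) {
    stop("`reference` must have the same number of steps as `traj`", call. = FALSE)
  }
  below <- traj$k_pos < ref_trace * (1 - rel_tol)

  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) {
    return(empty_suppression_report(baseline, min(traj$k_pos / ref_trace) * baseline,
                                    saccade, reason = "no sub-baseline samples"))
  }
  # the run around the saccade: prefer one containing onset, else the nearest
  # within one delay + saccade duration of it
  run_t0 <- traj$time[starts[runs]]
  run_t1 <- traj$time[ends[runs]] + dt
  contains <- run_t0 <= onset & run_t1 > onset
  sel <- if (any(contains)) {
    runs[which(contains)[1]]
  } else {
    d <- pmax(run_t0 - onset, onset - run_t1, 0)
    cand <- which(d <= cfg$delta_t + saccade$duration)
    if (length(cand) == 0L) {
      return(empty_suppression_report(baseline, min(traj$k_pos[in_base]),
                                      saccade,
                                      reason = "no sub-baseline run near the saccade"))
    }
    runs[cand[which.min(d[cand])]]
  }
  ri <- which(runs == sel)
  i0 <- starts[sel]
  i1 <- ends[sel]
  t0 <- traj$time[i0]
  t1 <- traj$time[i1] + dt
  min_gain <- min(traj$k_pos[i0:i1])
  base_at_min <- ref_trace[i0:i1][which.min(traj$k_pos[i0:i1])]

  post <- traj$time >= t1 & traj$time < t1 + 0.100
  structure(list(
    suppressed = TRUE,
    baseline_gain = baseline,
    min_gain = min_gain,
    relative_drop = 1 - min_gain / base_at_min,
    onset_timelocked = t0 - onset,
    offset_timelocked = t1 - onset,
    onset_stimlocked = t0 - onset - cfg$delta_t,
    offset_stimlocked = t1 - onset - cfg$delta_t,
    enhancement_gain = if (any(post)) max(traj$k_pos[post]) else NA_real_,
    saccade = saccade,
    rel_tol = rel_tol,
    delta_t = cfg$delta_t
  ), class = "suppression_report")
}

# end of the pre-movement fixation: first movement epoch start, else the
# first surprise jump, else one delay before saccade onset
baseline_end_time <- function(traj, cfg, onset) {
  task <- attr(traj, "task")
  if (!is.null(task)) {
    kinds <- task$epochs$kind
    if (any(kinds == "movement")) {
      return(cumsum(task$epochs$duration)[which(kinds == "movement")[1] - 1L])
    }
    if (nrow(task$jumps)) return(min(task$jumps$time))
  }
  onset - cfg$delta_t
}

empty_suppression_report <- function(baseline = NA_real_, min_gain = NA_real_,
                                     saccade = NULL, reason = "") {
  structure(list(
    suppressed = FALSE, baseline_gain = baseline, min_gain = min_gain,
    relative_drop = if (is.na(baseline)) NA_real_ else max(0, 1 - min_gain / baseline),
    onset_timelocked = NA_real_, offset_timelocked = NA_real_,
    onset_stimlocked = NA_real_, offset_stimlocked = NA_real_,
    enhancement_gain = NA_real_, saccade = saccade, reason = reason
  ), class = "suppression_report")
}

#' @export
print.suppression_report <- function(x, ...) {
  if (!x$suppressed) {
    cat("<suppression_report> no suppression window (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<suppression_report>\n")
  cat(sprintf("  baseline gain %.4g, minimum %.4g (relative drop %.1f%%)\n",
              x$baseline_gain, x$min_gain, 100 * x$relative_drop))
  cat(sprintf("  time-locked window: %+.0f to %+.0f ms re saccade onset\n",
              1000 * x$onset_timelocked, 1000 * x$offset_timelocked))
  cat(sprintf("  stimulus-locked:    %+.0f to %+.0f ms re saccade onset\n",
              1000 * x$onset_stimlocked, 1000 * x$offset_stimlocked))
  invisible(x)
}

#' Suppression magnitude and timing across saccade amplitudes
#'
#' Runs one noise-free saccade per amplitude and reports the suppression
#' depth and window timing. Under signal-dependent noise the per-command
#' variance grows with `u^2`, so larger saccades suppress more while the
#' window timing -- set by the delay plus the movement duration -- stays
#' nearly constant.
#'
#' @param amplitudes Saccade amplitudes in degrees (positive, sorted).
#' @param config A [sacc_config()].
#' @param ... Passed to [make_saccade_task()].
#' @return A tibble with one row per amplitude: baseline, minimum and
#'   relative drop of the position weight, window bounds (ms, time-locked),
#'   peak extrapolation position variance, peak command, saccade duration
#'   and peak velocity.
#' @export
amplitude_scaling <- function(amplitudes, config = sacc_config(), ...) {
  stopifnot(all(amplitudes > 0), !is.unsorted(amplitudes))
  purrr::map_dfr(amplitudes, function(a) {
    traj <- run_closed_loop(make_saccade_task(a, config, ...), config)
    ev <- detect_saccades(traj)
    rep_ <- suppression_window(traj, saccade = ev[1, ])
    tibble::tibble(
      amplitude = a,
      baseline_gain = rep_$baseline_gain,
      min_gain = rep_$min_gain,
      relative_drop = rep_$relative_drop,
      onset_ms = 1000 * rep_$onset_timelocked,
      offset_ms = 1000 * rep_$offset_timelocked,
      peak_v_pos = max(traj$v_pos),
      peak_abs_u = max(abs(traj$u)),
      duration_ms = 1000 * ev$duration[1],
      peak_velocity = ev$peak_velocity[1]
    )
  })
}

#' Catch-up saccade versus smooth pursuit initiation
#'
#' Simulates the same target velocity jump twice: once with a compensating
#' backward position jump (`p_jump = -v_jump * delta_t`, cancelling the
#' position error that accumulates over the delay, so pursuit starts
#' smoothly) and once without (the accumulated error is corrected by a
#' catch-up saccade). Because the sensory weight also falls slowly with
#' eccentricity as the eye tracks, the smooth-initiation run serves as the
#' time-matched reference trace: saccade-evoked suppression is the transient
#' drop of the uncompensated run below it.
#'
#' @param v_jump Target velocity after the jump, deg/s.
#' @param config A [sacc_config()].
#' @param p_jump Compensating displacement for the smooth variant (default
#'   `-v_jump * delta_t`).
#' @param ... Passed to [make_pursuit_task()].
#' @return A two-row tibble (`variant` = "catch_up" / "smooth") with the
#'   number of detected saccades, the relative drop below the reference
#'   trace, and the window bounds in ms (NA when no window exists).
#' @export
pursuit_contrast <- function(v_jump, config = sacc_config(),
                             p_jump = -v_jump * config$delta_t, ...) {
  if (v_jump == 0 && p_jump == 0) {
    task <- make_pursuit_task(0, 0, config, ...)
    traj <- run_closed_loop(task, config)
    return(purrr::map_dfr(c("catch_up", "smooth"), function(v) {
      contrast_row(v, traj, traj, config)
    }))
  }
  traj_cu <- run_closed_loop(make_pursuit_task(v_jump, 0, config, ...), config)
  traj_sm <- run_closed_loop(make_pursuit_task(v_jump, p_jump, config, ...), config)
  dplyr::bind_rows(
    contrast_row("catch_up", traj_cu, traj_sm, config),
    contrast_row("smooth", traj_sm, traj_sm, config)
  )
}

contrast_row <- function(variant, traj, reference, config) {
  ev <- detect_saccades(traj)
  rep_ <- suppression_window(traj,
    saccade = if (nrow(ev)) ev[1, ] else NULL,
    reference = reference, config = config
  )
  tibble::tibble(
    variant = variant,
    n_saccades = nrow(ev),
    saccade_amplitude = if (nrow(ev)) ev$amplitude[1] else NA_real_,
    suppressed = rep_$suppressed,
    relative_drop = if (rep_$suppressed) rep_$relative_drop else 0,
    onset_ms = 1000 * rep_$onset_timelocked,
    offset_ms = 1000 * rep_$offset_timelocked,
    terminal_error = abs(traj$eye_pos[nrow(traj)] - traj$target_pos[nrow(traj)])
  )
}

#' Monte-Carlo validation of the extrapolation covariance
#'
#' Independent check of the analytic extrapolation-error covariance: roll
#' the open-loop stochastic dynamics forward under a fixed command schedule
#' many times, extrapolate each final delayed observation to the present,
#' and compare the empirical covariance of the extrapolation error with the
#' analytic `Vt` entrywise, in units of the Monte-Carlo standard error.
#'
#' The rollouts inject the noise channels the analytic covariance
#' propagates: the multiplicative control noise and the sensory noise. The
#' additive process noise (which the printed covariance does not carry) can
#' be switched on with `include_additive` to quantify that approximation.
#' The analytic side is computed without the target-block copy, which models
#' feedback uncertainty rather than plant noise.
#'
#' @param u_schedule Command schedule (length >= L); the final L commands
#'   fill the delay buffer at comparison time.
#' @param n_rollouts Number of rollouts (>= 1000).
#' @param seed RNG seed.
#' @param config A [sacc_config()].
#' @param include_additive Also inject the additive process noise.
#' @return An `mc_oracle` list: `V_analytic`, `V_empirical`, entrywise
#'   z-scores `z`, `max_abs_z`, and `n_rollouts`.
#' @export
mc_covariance_oracle <- function(u_schedule, n_rollouts = 10000, seed = 1,
                                 config = sacc_config(),
                                 include_additive = FALSE) {
  stopifnot(n_rollouts >= 1000)
  model <- discretize(build_plant(config), config)
  L <- model$L
  ns <- length(u_schedule)
  if (ns < L) stop("`u_schedule` must cover at least L = ", L, " steps", call. = FALSE)
  set.seed(seed)

  X <- matrix(0, 4, n_rollouts) # start at the origin equilibrium
  X_delayed <- NULL
  for (t in seq_len(ns)) {
    if (t == ns - L + 1L) X_delayed <- X
    eps <- stats::rnorm(n_rollouts)
    bu <- as.numeric(model$Bd) %o% (u_schedule[t] * (1 + model$alpha * eps))
    X <- model$Ad %*% X + bu
    if (include_additive) {
      X <- X + as.numeric(sqrt(config$xi_scale) * model$Bd) %o% stats::rnorm(n_rollouts)
    }
  }
  if (ns == L) X_delayed <- matrix(0, 4, n_rollouts)

  sigma <- sqrt(config$sigma_scale) * matrix(stats::rnorm(4 * n_rollouts), 4)
  Y <- X_delayed + sigma
  u_buf <- u_schedule[(ns - L + 1L):ns]
  # vectorized extrapolation: same linear map for every rollout
  X_ex <- model$ML %*% Y + as.numeric(model$mkb %*% rev(u_buf))
  err <- X_ex - X

  V_emp <- stats::cov(t(err))
  V_ana <- extrapolation_covariance(u_buf, model, copy = FALSE)
  se <- sqrt((diag(V_ana) %o% diag(V_ana) + V_ana^2) / (n_rollouts - 1))
  z <- (V_emp - V_ana) / se
  structure(list(
    V_analytic = V_ana, V_empirical = V_emp, z = z,
    max_abs_z = max(abs(z)), n_rollouts = n_rollouts,
    u_schedule = u_schedule, include_additive = include_additive
  ), class = "mc_oracle")
}

#' @export
print.mc_oracle <- function(x, ...) {
  cat("<mc_oracle>", x$n_rollouts, "rollouts, max |z| =",
      format(x$max_abs_z, digits = 3), "\n")
  invisible(x)
}
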