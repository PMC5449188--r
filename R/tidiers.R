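#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a suppression report
#'
#' @param x A `suppression_report`.
#' @param ... Unused.
#' @return One-row tibble; window bounds in milliseconds relative to
#'   saccade onset, gains dimensionless.
#' @export
tidy.suppression_report <- function(x, ...) {
  tibble::tibble(
    suppressed = x$suppressed,
    baseline_gain = x$baseline_gain,
    min_gain = x$min_gain,
    relative_drop = x$relative_drop,
    onset_timelocked_ms = 1000 * x$onset_timelocked,
    offset_timelocked_ms = 1000 * x$offset_timelocked,
    onset_stimlocked_ms = 1000 * x$onset_stimlocked,
    offset_stimlocked_ms = 1000 * x$offset_stimlocked,
    enhancement_gain = x$enhancement_gain
  )
}

#' @rdname tidy.suppression_report
#' @export
glance.suppression_report <- function(x, ...) {
  tibble::tibble(
    suppressed = x$suppressed,
    relative_drop = x$relative_drop,
    duration_ms = 1000 * (x$offset_timelocked - x$onset_timelocked)
  )
}

#' Tidy a Monte-Carlo covariance comparison
#'
#' @param x An `mc_oracle`.
#' @param ... Unused.
#' @return A 16-row tibble: one row per covariance entry with the analytic
#'   and empirical values and the z-score.
#' @export
tidy.mc_oracle <- function(x, ...) {
  nm <- c("eye_pos", "eye_vel", "target_pos", "target_vel")
  grid <- expand.grid(row = 1:4, col = 1:4)
  tibble::tibble(
    row = nm[grid$row], col = nm[grid$col],
    analytic = as.numeric(x$V_analytic),
    empirical = as.numeric(x$V_empirical),
    z = as.numeric(x$z)
  )
}

#' @rdname tidy.mc_oracle
#' @export
glance.mc_oracle <- function(x, ...) {
  tibble::tibble(n_rollouts = x$n_rollouts, max_abs_z = x$max_abs_z,
                 include_additive = x$include_additive)
}
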