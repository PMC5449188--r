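trajectory_schema <- function() {
  c("time", "eye_pos", "eye_vel", "target_pos", "target_vel",
    "eye_pos_hat", "eye_vel_hat", "target_pos_hat", "target_vel_hat",
    "eye_pos_prior", "eye_vel_prior", "target_pos_prior", "target_vel_prior",
    "u", "control_var", "v_pos", "v_trace",
    "k_pos", "k_vel", "k_tpos", "k_tvel",
    "p_pos", "p_vel", "p_tpos", "p_tvel")
}

#' Write / read a trajectory as CSV with a JSON manifest
#'
#' The CSV holds the per-step record with a fixed, versioned column schema;
#' doubles are written in shortest round-trip representation so
#' `read_trajectory(write_trajectory(x))` reproduces every value exactly. A
#' JSON sidecar (same path with extension `.json`) records the resolved
#' configuration, the task and the seed, so a run can be reproduced from its
#' manifest alone.
#'
#' @param traj A `sacc_trajectory`.
#' @param path Output CSV path; the manifest goes to `<path>.json` (with the
#'   `.csv` extension replaced).
#' @param manifest Write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, manifest = TRUE) {
  stopifnot(all(trajectory_schema() %in% names(traj)))
  readr::write_csv(traj[trajectory_schema()], path)
  if (manifest) {
    cfg <- attr(traj, "config")
    task <- attr(traj, "task")
    man <- list(
      schema = "sacc_trajectory_v1",
      package_version = as.character(utils::packageVersion("saccsim")),
      seed = attr(traj, "seed"),
      config = if (!is.null(cfg)) unclass(cfg),
      task = if (!is.null(task)) list(
        epochs = task$epochs, jumps = task$jumps
      )
    )
    jsonlite::write_json(man, manifest_path(path), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

manifest_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' @rdname write_trajectory
#' @return `read_trajectory()`: the trajectory tibble; the config and task
#'   are re-attached from the manifest when the sidecar is present.
#' @export
read_trajectory <- function(path) {
  # base read.csv: its double parser is exact to the last ulp, so the
  # shortest round-trip representation written by write_trajectory() is
  # recovered bit for bit
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, trajectory_schema())) {
    stop("trajectory schema mismatch in '", path,
         "': expected sacc_trajectory_v1 columns", call. = FALSE)
  }
  out <- tryCatch(
    utils::read.csv(path, colClasses = "numeric"),
    error = function(e) stop("malformed trajectory file '", path, "': ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("malformed trajectory file '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  out <- tibble::as_tibble(out)
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    man <- jsonlite::read_json(mp, simplifyVector = TRUE)
    if (!is.null(man$config)) {
      attr(out, "config") <- do.call(sacc_config, man$config[names(man$config) %in%
                                                               names(formals(sacc_config))])
    }
    if (!is.null(man$task)) {
      epochs <- tibble::as_tibble(man$task$epochs)
      jumps <- tibble::as_tibble(man$task$jumps)
      if (nrow(jumps) == 0L) {
        jumps <- tibble::tibble(time = numeric(), d_pos = numeric(),
                                d_vel = numeric(), known = logical())
      }
      attr(out, "task") <- new_task(epochs, jumps, attr(out, "config"))
    }
    attr(out, "seed") <- man$seed
  }
  class(out) <- c("sacc_trajectory", class(out))
  out
}

#' Load / save a model configuration as YAML
#'
#' Unspecified fields take the package defaults. Time-valued fields
#' (`tau1`, `tau2`, `dt`, `delta_t`) accept either bare numbers in seconds
#' or strings with a unit suffix (`"224 ms"`, `"0.1 s"`); everything is
#' stored in seconds. Unknown keys, non-positive values, or a delay that is
#' not a multiple of `dt` raise descriptive errors.
#'
#' @param path YAML file path. An empty file yields the full default
#'   configuration.
#' @return A `sacc_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(sacc_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  time_fields <- c("tau1", "tau2", "dt", "delta_t")
  for (nm in intersect(names(raw), time_fields)) {
    raw[[nm]] <- parse_seconds(raw[[nm]], nm)
  }
  do.call(sacc_config, raw)
}

parse_seconds <- function(v, field) {
  if (is.numeric(v)) return(v)
  if (is.character(v) && length(v) == 1L) {
    m <- regmatches(v, regexec("^\\s*([-0-9.eE+]+)\\s*(ms|s)\\s*$", v))[[1]]
    if (length(m) == 3L) {
      val <- as.numeric(m[2])
      if (is.finite(val)) return(if (m[3] == "ms") val / 1000 else val)
    }
  }
  stop("configuration error: cannot parse `", field, "` value '", v,
       "' as a time (use seconds or 'N ms')", call. = FALSE)
}

#' @rdname load_config
#' @param config A `sacc_config` to serialize.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sacc_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Generate the canonical reference runs
#'
#' Writes four noise-free trajectories with manifests: the 20-deg saccade,
#' the two pursuit variants (velocity jump with and without compensating
#' position jump), and a control run with `alpha = 0` (no signal-dependent
#' noise, hence no suppression). These are the runs every analysis in the
#' package is demonstrated on.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifests; the runs themselves are
#'   noise-free mean rollouts, so the files are bit-identical across calls.
#' @return Named character vector of the CSV paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sacc_config()
  cfg0 <- sacc_config(alpha = 0)
  runs <- list(
    saccade_20deg = run_closed_loop(make_saccade_task(20, cfg), cfg),
    pursuit_catch_up = run_closed_loop(make_pursuit_task(20, 0, cfg), cfg),
    pursuit_smooth = run_closed_loop(
      make_pursuit_task(20, -20 * cfg$delta_t, cfg), cfg),
    saccade_alpha0 = run_closed_loop(make_saccade_task(20, cfg0), cfg0)
  )
  paths <- vapply(names(runs), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_trajectory(runs[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
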