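config_defaults <- function() {
  list(
    pk_closed = 8.5, pk_open = 4.3, kd = 100,
    alpha = 0.03, beta = 0.55,
    n_steps = 1e5, mc_interval = 10L, p_conf_attempt = 0.01,
    seed = 1L, burn_in = 0.1,
    window = 100L, persistence = 50L, block_length = 100L
  )
}

#' Load and validate a run configuration
#'
#' Reads a flat YAML file of key-value pairs; unset keys take documented
#' defaults (the reference parameter set: microscopic pKa 8.5 closed /
#' 4.3 open, K_D = 100, signal plateaus 0.03 / 0.55, and the simulator
#' and estimator defaults). Unknown keys are an error, as are values
#' violating their constraints. Explicit arguments in `overrides` win
#' over the file, which wins over defaults.
#'
#' @param path Path to a YAML config file, or NULL for pure defaults.
#' @param overrides Named list applied on top of the file (e.g. parsed
#'   command-line flags).
#' @return A validated named list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(user)] <- user
  }
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown override key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  check <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  check(is.finite(cfg$pk_closed) && is.finite(cfg$pk_open),
        "pk_closed and pk_open must be finite")
  check(is.finite(cfg$kd) && cfg$kd > 0, "kd must be positive")
  check(cfg$alpha != cfg$beta, "alpha and beta must differ")
  check(cfg$n_steps >= 1, "n_steps must be positive")
  check(cfg$mc_interval >= 1, "mc_interval must be >= 1")
  check(cfg$p_conf_attempt >= 0 && cfg$p_conf_attempt <= 1,
        "p_conf_attempt must lie in [0, 1]")
  check(cfg$burn_in >= 0 && cfg$burn_in < 1, "burn_in must lie in [0, 1)")
  check(cfg$window >= 1, "window must be >= 1")
  check(cfg$block_length >= 1, "block_length must be >= 1")
  structure(cfg, class = "run_config")
}

#' Write a trajectory to headered CSV with a JSON sidecar manifest
#'
#' The CSV carries the frame table (columns `time_ns`, `conformation`,
#' `protonated`, `d_asp30_leu130`, `d_asp35_asp129`, `sasa`); the
#' manifest (`<path>.manifest.json`) records pH, seed, frame step and the
#' cycle parameters so a written trajectory is self-describing and
#' round-trips exactly through [read_trajectory()].
#'
#' @param traj A `cphmd_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cphmd_trajectory"))
  data.table::fwrite(as.data.frame(traj), path)
  manifest <- list(ph = attr(traj, "ph"), seed = attr(traj, "seed"),
                   step_ns = attr(traj, "step_ns"),
                   burn_in = attr(traj, "burn_in"),
                   cycle = attr(traj, "cycle"),
                   n_frames = nrow(traj))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path CSV path; the `<path>.manifest.json` sidecar is read when
#'   present to restore the pH, seed and step metadata.
#' @return A `cphmd_trajectory` data.frame.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path))
  needed <- c("time_ns", "conformation", "protonated")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    stop("trajectory file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mpath <- paste0(path, ".manifest.json")
  meta <- if (file.exists(mpath)) jsonlite::read_json(mpath, simplifyVector = TRUE)
          else list()
  structure(df,
            ph = meta$ph %||% NA_real_, seed = meta$seed %||% NA_integer_,
            step_ns = meta$step_ns %||% NA_real_,
            burn_in = meta$burn_in %||% 0.1,
            cycle = meta$cycle,
            class = c("cphmd_trajectory", "data.frame"))
}

#' Write a titration table (pH, protonated counts, totals) as CSV
#'
#' @param series Data.frame with columns `ph`, `n_prot`, `n_total` (an
#'   optional `conformation` column is preserved).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  stopifnot(is.data.frame(series),
            all(c("ph", "n_prot", "n_total") %in% names(series)))
  data.table::fwrite(series, path)
  invisible(path)
}

#' Read a titration table written by [write_titration()]
#' @param path CSV path.
#' @return A data.frame with columns `ph`, `n_prot`, `n_total` (and
#'   `conformation` when present).
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("titration file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(c("ph", "n_prot", "n_total"), names(df))
  if (length(missing) > 0L)
    stop("titration file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' Write a scalar result record as JSON
#'
#' Numbers are written at full double precision; any printed-precision
#' rounding belongs in report text, not in the stored record. `pka_estimate`
#' and `thermo_cycle` objects are flattened to plain named lists first.
#'
#' @param record Named list (arbitrarily nested) of serialisable values.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_results <- function(record, path) {
  flatten <- function(x) {
    if (inherits(x, "pka_estimate") || inherits(x, "thermo_cycle") ||
        inherits(x, "run_config"))
      return(lapply(unclass(x), flatten))
    if (is.list(x)) return(lapply(x, flatten))
    x
  }
  jsonlite::write_json(flatten(record), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
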