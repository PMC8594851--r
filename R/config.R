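#' Full run configuration
#'
#' Ties together the force-law parameters, the initial-condition spec and
#' the stop criteria for one simulation.
#'
#' @param model An [fvm_params()] object.
#' @param init An [fvm_init()] spec.
#' @param stop An [fvm_stop()] object.
#' @param adaptive Adaptive time stepping (default `TRUE`; with `FALSE`
#'   every iteration uses `DT = 1`).
#' @param record_trajectory Keep per-iteration positions in the result
#'   (memory-heavy for long runs; off by default).
#' @return An object of class `fvm_config`.
#' @export
fvm_config <- function(model = fvm_params(), init = fvm_init(),
                       stop = fvm_stop(), adaptive = TRUE,
                       record_trajectory = FALSE) {
  stopifnot(inherits(model, "fvm_params"), inherits(init, "fvm_init"),
            inherits(stop, "fvm_stop"))
  structure(list(model = model, init = init, stop = stop,
                 adaptive = isTRUE(adaptive),
                 record_trajectory = isTRUE(record_trajectory)),
            class = "fvm_config")
}

# plain-list view used for YAML round-tripping and hashing
.config_as_list <- function(config) {
  init <- config$init
  list(
    model = unclass(config$model),
    init = list(n_agents = init$n_agents,
                spatial = lapply(init$spatial, unclass),
                mass = unclass(init$mass),
                max_mass = init$max_mass,
                equal_masses = init$equal_masses,
                seed = init$seed,
                injections = init$injections,
                geometry = if (is.null(init$geometry)) NULL else
                  apply(init$geometry, 1L, as.numeric, simplify = FALSE)),
    stop = unclass(config$stop),
    adaptive = config$adaptive,
    record_trajectory = config$record_trajectory)
}

#' Write a configuration to a YAML file
#' @param config An [fvm_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fvm_config <- function(config, path) {
  stopifnot(inherits(config, "fvm_config"))
  yaml::write_yaml(.config_as_list(config), path)
  invisible(path)
}

.known_keys <- list(
  top = c("model", "init", "stop", "adaptive", "record_trajectory"),
  model = c("g", "metric_weights", "distance_exponent", "aib",
            "coalescence_radius", "force_mode", "dimension",
            "visible_half_width"),
  init = c("n_agents", "spatial", "mass", "max_mass", "equal_masses",
           "seed", "injections", "geometry"),
  stop = c("tickstop", "agent_stop", "dt_stop"))

.reject_unknown <- function(x, section) {
  bad <- setdiff(names(x), .known_keys[[section]])
  if (length(bad))
    stop("unknown configuration key(s) in `", section, "`: ",
         paste(bad, collapse = ", "), call. = FALSE)
}

.dist_from_list <- function(x) {
  switch(x$kind,
    uniform = dist_uniform(),
    normal = dist_normal(x$mean, x$sd),
    exponential = dist_exponential(x$rate, x$offset),
    stop("unknown distribution kind: ", x$kind, call. = FALSE))
}

#' Read a configuration from a YAML file
#'
#' Missing sections fall back to the package defaults; unknown keys are
#' rejected with the offending key path. Values passed in `overrides`
#' (e.g. parsed command-line flags, as `model$aib = 100` style nested
#' lists) take precedence over the file.
#'
#' @param path YAML file written by [write_fvm_config()] or by hand.
#' @param overrides Optional nested list merged over the file's values.
#' @return An [fvm_config()] object.
#' @export
read_fvm_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  for (section in names(overrides)) {
    if (is.list(overrides[[section]])) {
      for (key in names(overrides[[section]]))
        raw[[section]][[key]] <- overrides[[section]][[key]]
    } else raw[[section]] <- overrides[[section]]
  }
  .reject_unknown(raw, "top")
  for (s in c("model", "init", "stop"))
    if (!is.null(raw[[s]])) .reject_unknown(raw[[s]], s)
  model <- do.call(fvm_params, raw$model %||% list())
  init_args <- raw$init %||% list()
  if (!is.null(init_args$spatial))
    init_args$spatial <- lapply(init_args$spatial, .dist_from_list)
  if (!is.null(init_args$mass))
    init_args$mass <- .dist_from_list(init_args$mass)
  if (!is.null(init_args$geometry))
    init_args$geometry <- do.call(rbind, init_args$geometry)
  init <- do.call(fvm_init, init_args)
  stop_crit <- do.call(fvm_stop, raw$stop %||% list())
  fvm_config(model = model, init = init, stop = stop_crit,
             adaptive = raw$adaptive %||% TRUE,
             record_trajectory = raw$record_trajectory %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the YAML rendering, stamped into CSV headers for provenance
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_fvm_config(config, tf)
  unname(tools::md5sum(tf))
}

# numbers at full double precision so re-analysis is lossless
.format_full <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  }
  df
}

.write_csv_with_hash <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(paste0("# config_hash: ", .config_hash(config)), con)
  utils::write.table(.format_full(df), con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Export the per-iteration step log as CSV
#'
#' One row per iteration, keyed by (run seed, iteration), with the
#' step-record fields (dt, elapsed time, peak distance, force sums,
#' counts). A comment line carries the md5 of the run's configuration;
#' numbers are written at full double precision.
#'
#' @param run An `fvm_run`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_step_log <- function(run, path) {
  df <- cbind(run_seed = run$seed, run$records)
  .write_csv_with_hash(df, path, run$config_echo)
}

#' Export a recorded trajectory as JSON lines
#'
#' One JSON object per iteration:
#' `{iteration, et, dt, agents: [{id, pos, m, M, group}]}`.
#'
#' @param run An `fvm_run` produced with `record_trajectory = TRUE`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(run, path) {
  if (is.null(run$trajectory))
    stop("run was not recorded with `record_trajectory = TRUE`",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(run$trajectory)) {
    snap <- run$trajectory[[i]]
    grp <- lengths(snap$members) > 1L
    agents <- lapply(seq_along(snap$ids), function(j) {
      list(id = snap$ids[j], pos = as.numeric(snap$positions[j, ]),
           m = snap$active_mass[j], M = snap$passive_mass[j],
           group = grp[j])
    })
    obj <- list(iteration = run$records$iteration[i],
                et = run$records$elapsed_time[i],
                dt = run$records$dt[i],
                agents = agents)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
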