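# one row of per-run outcomes for ensemble tables
.run_row <- function(run, params) {
  final <- run$final_population
  init <- run$initial_population
  n <- n_agents(final)
  drift <- sqrt(sum((center_of_attributes(final) -
                     center_of_attributes(init))^2))
  last_pct <- if (nrow(run$records)) run$records$repulsive_pct[nrow(run$records)]
              else 0
  data.frame(
    seed = run$seed,
    aib = params$aib,
    n_initial = n_agents(init),
    n_final_agents = n,
    n_final_groups = sum(is_group(final)),
    iterations = run$iterations,
    elapsed_time = run$elapsed_time,
    stop_reason = run$stop_reason,
    mdcn = if (n >= 2L) mdcn(final, params) else NA_real_,
    mean_pairwise = if (n >= 2L) mean_pairwise_distance(final, params)
                    else NA_real_,
    mean_dist_origin = mean_origin_distance(final),
    centroid_drift = drift,
    repulsive_pct_final = last_pct,
    largest_mass_share = max(final$active_mass) / sum(final$active_mass))
}

#' Run an ensemble of independent simulations
#'
#' Runs `n_runs` simulations that differ only in their RNG seed
#' (consecutive seeds `base_seed + 0 .. n_runs - 1`), and aggregates the
#' per-run outcomes. Deterministic given `base_seed`.
#'
#' @param config An [fvm_config()]; its init seed is overridden per run.
#' @param n_runs Number of runs (>= 1).
#' @param base_seed First seed of the consecutive block.
#' @param keep_finals Keep each run's final population (needed for pooled
#'   angle/mass statistics; default `TRUE`).
#' @return An object of class `fvm_ensemble`: a list with `runs` (data
#'   frame, one row per run), `finals` (list of final populations, or
#'   `NULL`), `summary` (means and SDs of the headline outcomes),
#'   `params`, `base_seed`.
#' @export
run_ensemble <- function(config, n_runs, base_seed = 1L,
                         keep_finals = TRUE) {
  stopifnot(inherits(config, "fvm_config"), n_runs >= 1L)
  rows <- vector("list", n_runs)
  finals <- if (keep_finals) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$init$seed <- as.integer(base_seed + i - 1L)
    run <- tryCatch(fvm_run(cfg), error = function(e) {
      stop("ensemble run with seed ", base_seed + i - 1L, " failed: ",
           conditionMessage(e), call. = FALSE)
    })
    rows[[i]] <- .run_row(run, config$model)
    if (keep_finals) finals[[i]] <- run$final_population
  }
  runs <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  summary <- list(
    key = config$model$aib,
    n_runs = n_runs,
    mean_final_agents = mean(runs$n_final_agents),
    sd_final_agents = sd0(runs$n_final_agents),
    mean_final_groups = mean(runs$n_final_groups),
    sd_final_groups = sd0(runs$n_final_groups),
    mean_mdcn = mean(runs$mdcn, na.rm = TRUE),
    sd_mdcn = sd0(runs$mdcn[!is.na(runs$mdcn)]),
    mean_dist_origin = mean(runs$mean_dist_origin),
    mean_pairwise = mean(runs$mean_pairwise, na.rm = TRUE))
  structure(list(runs = runs, finals = finals, summary = summary,
                 params = config$model, base_seed = base_seed),
            class = "fvm_ensemble")
}

#' @export
print.fvm_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<fvm_ensemble> AIB = %g, %d runs: %.2f +- %.2f final",
                     " agents, MDCN %.1f\n"),
              s$key, s$n_runs, s$mean_final_agents, s$sd_final_agents,
              s$mean_mdcn))
  invisible(x)
}

#' Sweep the Attribute Influence Bound
#'
#' One ensemble per AIB value, everything else fixed. Seeds advance in
#' consecutive blocks (`n_runs` per AIB) so every run in the sweep has a
#' distinct seed.
#'
#' @param aib_values Numeric vector of AIB values.
#' @param base_config An [fvm_config()] whose model AIB is replaced per
#'   ensemble.
#' @param n_runs Runs per AIB value.
#' @param base_seed First seed of the whole sweep.
#' @param keep_finals Passed to [run_ensemble()].
#' @return A list of class `fvm_sweep`: `ensembles` (one
#'   [run_ensemble()] result per AIB), `summary` (data frame, one row per
#'   AIB), `runs` (all per-run rows bound together).
#' @export
sweep_aib <- function(aib_values, base_config, n_runs, base_seed = 1L,
                      keep_finals = TRUE) {
  stopifnot(length(aib_values) >= 1L)
  ensembles <- vector("list", length(aib_values))
  for (k in seq_along(aib_values)) {
    cfg <- base_config
    cfg$model <- do.call(fvm_params, utils::modifyList(
      unclass(base_config$model), list(aib = aib_values[k])))
    ensembles[[k]] <- run_ensemble(cfg, n_runs,
                                   base_seed + (k - 1L) * n_runs,
                                   keep_finals = keep_finals)
  }
  summary <- do.call(rbind, lapply(ensembles, function(e)
    as.data.frame(e$summary)))
  runs <- do.call(rbind, lapply(ensembles, `[[`, "runs"))
  structure(list(ensembles = ensembles, summary = summary, runs = runs),
            class = "fvm_sweep")
}

#' Fit the exponential decay of surviving agents with AIB
#'
#' The mean number of final agents falls approximately exponentially
#' toward a floor as the AIB grows. This fits ordinary least squares to
#' `ln(mean_final_agents - floor)` versus AIB; points at or below the
#' floor are excluded with a warning.
#'
#' @param summary A data frame with columns `key` (AIB) and
#'   `mean_final_agents`, e.g. the `summary` of [sweep_aib()].
#' @param floor Asymptotic number of surviving agents subtracted before
#'   the log transform (default 2.2).
#' @return A list with `slope`, `intercept`, `r_squared`, `n_used`, and
#'   the fitted `lm` object.
#' @export
fit_agent_decay <- function(summary, floor = 2.2) {
  usable <- summary$mean_final_agents > floor
  if (any(!usable))
    warning(sum(!usable), " point(s) at or below the floor excluded")
  if (sum(usable) < 2L)
    stop("need at least 2 points above the floor to fit", call. = FALSE)
  df <- data.frame(aib = summary$key[usable],
                   lnn = log(summary$mean_final_agents[usable] - floor))
  fit <- stats::lm(lnn ~ aib, data = df)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared,
       n_used = sum(usable),
       fit = fit)
}

#' Pooled final-state geometry for runs ending with exactly k agents
#'
#' Pools the angular gaps between adjacent final agents, and the final
#' agent masses, over all runs of one or more ensembles that ended with
#' exactly `k` agents. With `k` survivors the gaps per run sum to 360
#' degrees, so the pooled gap mean is 360/k by construction; the spread
#' around it measures how symmetric the final arrangements are. For
#' `k = 2` the two gaps per run are the minor and the reflex angle
#' between the survivors, so the pooled SD equals the RMS deviation of
#' their separation from 180 degrees.
#'
#' @param ensembles An `fvm_ensemble`, an `fvm_sweep`, or a list of
#'   ensembles (each needs its `finals` kept).
#' @param k Number of final agents to condition on.
#' @return A list with `n_runs`, `gaps`, `gap_mean`, `gap_sd`, `masses`,
#'   `mass_mean`, `mass_sd`; errors if no run qualifies.
#' @export
final_state_geometry <- function(ensembles, k) {
  if (inherits(ensembles, "fvm_ensemble")) ensembles <- list(ensembles)
  if (inherits(ensembles, "fvm_sweep")) ensembles <- ensembles$ensembles
  gaps <- numeric(0)
  masses <- numeric(0)
  n_runs <- 0L
  for (e in ensembles) {
    if (is.null(e$finals))
      stop("ensemble was run with `keep_finals = FALSE`", call. = FALSE)
    for (final in e$finals) {
      if (n_agents(final) != k) next
      n_runs <- n_runs + 1L
      gaps <- c(gaps, adjacent_angle_gaps(final))
      masses <- c(masses, final$active_mass)
    }
  }
  if (n_runs == 0L)
    stop("no run ended with exactly ", k, " agents", call. = FALSE)
  list(n_runs = n_runs, gaps = gaps, gap_mean = mean(gaps),
       gap_sd = stats::sd(gaps), masses = masses,
       mass_mean = mean(masses), mass_sd = stats::sd(masses))
}

#' Consensus probability over a grid of initial-distribution centers
#'
#' Moves the center of the initial spatial distribution over a grid of
#' points and measures, per center, the fraction of runs ending in total
#' consensus (one final agent holding every original member id) and the
#' fraction reaching near consensus (the largest final agent holding at
#' least 90% of the total active mass). Run with a large AIB so all
#' agents can communicate.
#'
#' @param centers Two-column matrix of center coordinates.
#' @param base_config An [fvm_config()] whose spatial means are replaced
#'   per center (Standard Conditions with AIB 180 is the usual choice).
#' @param n_runs Runs per center.
#' @param base_seed First seed; each center consumes a consecutive block
#'   of `n_runs` seeds.
#' @param mass_threshold Near-consensus mass share (default 0.9).
#' @return A data frame with columns `x`, `y`, `p_consensus`, `p_90`;
#'   `p_consensus <= p_90` for every cell by construction.
#' @export
consensus_grid <- function(centers, base_config, n_runs, base_seed = 1L,
                           mass_threshold = 0.9) {
  centers <- as.matrix(centers)
  stopifnot(ncol(centers) == base_config$model$dimension)
  out <- vector("list", nrow(centers))
  for (ci in seq_len(nrow(centers))) {
    cfg <- base_config
    cfg$init$spatial <- lapply(seq_len(ncol(centers)), function(k) {
      s <- cfg$init$spatial[[min(k, length(cfg$init$spatial))]]
      if (s$kind != "normal")
        stop("consensus grid requires normal spatial distributions",
             call. = FALSE)
      dist_normal(centers[ci, k], s$sd)
    })
    n_cons <- n_near <- 0L
    for (r in seq_len(n_runs)) {
      cfg$init$seed <- as.integer(base_seed + (ci - 1L) * n_runs + r - 1L)
      run <- fvm_run(cfg)
      final <- run$final_population
      total_members <- length(unlist(final$members))
      if (n_agents(final) == 1L &&
          length(final$members[[1L]]) == total_members)
        n_cons <- n_cons + 1L
      if (max(final$active_mass) / sum(final$active_mass) >= mass_threshold)
        n_near <- n_near + 1L
    }
    out[[ci]] <- data.frame(x = centers[ci, 1L], y = centers[ci, 2L],
                            p_consensus = n_cons / n_runs,
                            p_90 = n_near / n_runs)
  }
  do.call(rbind, out)
}

#' Export per-run ensemble rows as CSV
#'
#' One row per run (seed, AIB, counts, elapsed time, stop reason, final
#' distance metrics, centroid drift, mass share), with a config-hash
#' comment line when a config is supplied.
#'
#' @param x An `fvm_ensemble`, `fvm_sweep`, or a per-run data frame.
#' @param path Output CSV path.
#' @param config Optional [fvm_config()] hashed into the header.
#' @return `path`, invisibly.
#' @export
write_ensemble_csv <- function(x, path, config = NULL) {
  runs <- if (is.data.frame(x)) x else x$runs
  .write_csv_with_hash(runs, path, config)
}
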