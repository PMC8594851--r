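#' Adaptive time step from the peak trial displacement
#'
#' The trial displacements of all agents are computed at `DT = 1`; the
#' largest one is the peak distance. The realised time step is then chosen
#' so that the largest actual displacement equals the Coalescence Radius:
#' `DT^2 = CR / PeakDistance`. Weak forces (small peak) give a large DT,
#' strong forces a small one, so the motion stays smooth while the number
#' of iterations stays low.
#'
#' @param peak_distance Largest trial displacement magnitude at `DT = 1`.
#' @param cr Coalescence radius.
#' @return The positive time step `sqrt(cr / peak_distance)`.
#'   `peak_distance = 0` means no agent would move at all: the run is at
#'   equilibrium and no finite step exists, signalled as an error of class
#'   `fvm_equilibrium`.
#' @examples
#' adaptive_dt(0.2, 0.2)        # 1
#' adaptive_dt(0.2 / 16, 0.2)   # 4
#' @export
adaptive_dt <- function(peak_distance, cr) {
  if (peak_distance < 0) stop("`peak_distance` must be >= 0", call. = FALSE)
  if (cr <= 0) stop("`cr` must be positive", call. = FALSE)
  if (peak_distance == 0)
    stop(structure(class = c("fvm_equilibrium", "error", "condition"),
                   list(message = "population is at equilibrium: no agent moves",
                        call = sys.call(-1))))
  sqrt(cr / peak_distance)
}

# internal union-find; always attaches the larger root to the smaller, so a
# component's root is its smallest row index
.components_under_cr <- function(positions, params) {
  n <- nrow(positions)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- attribute_distance(positions[i, ], positions[j, ], params)
        if (d < params$coalescence_radius) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge agents closer than the Coalescence Radius into groups
#'
#' Agents (individual or group) whose attribute distance is strictly less
#' than CR after an iteration are merged. Merging is transitive within one
#' pass: the connected components of the "closer than CR" graph each
#' collapse to a single agent, so the result does not depend on the order
#' in which pairs are examined. The merged agent sits at the position of
#' the component member with the greatest active mass (ties broken by the
#' lowest id), carries the summed active and passive masses, and absorbs
#' all member ids. Groups are permanent: nothing ever splits one.
#'
#' @param pop An [fvm_population()].
#' @param params An [fvm_params()] object.
#' @return A (possibly smaller) `fvm_population`.
#' @export
merge_pass <- function(pop, params) {
  n <- n_agents(pop)
  if (n < 2L) return(pop)
  roots <- .components_under_cr(pop$positions, params)
  if (!anyDuplicated(roots)) return(pop)
  keep_roots <- unique(roots)  # ascending order of first occurrence
  d <- ncol(pop$positions)
  new_pos <- matrix(0, length(keep_roots), d)
  new_active <- new_passive <- numeric(length(keep_roots))
  new_ids <- integer(length(keep_roots))
  new_members <- vector("list", length(keep_roots))
  for (k in seq_along(keep_roots)) {
    idx <- which(roots == keep_roots[k])
    best <- idx[order(-pop$active_mass[idx], pop$ids[idx])][1L]
    new_pos[k, ] <- pop$positions[best, ]
    new_active[k] <- sum(pop$active_mass[idx])
    new_passive[k] <- sum(pop$passive_mass[idx])
    new_ids[k] <- pop$ids[best]
    new_members[[k]] <- sort(unlist(pop$members[idx]))
  }
  fvm_population(new_pos, new_active, new_passive, ids = new_ids,
                 members = new_members)
}

#' Advance the population by one iteration
#'
#' One iteration of the simulation loop, in pure R (the full run loop uses
#' the compiled engine; this reference path is convenient for inspecting a
#' single step). Net forces are computed for every agent from the pre-step
#' state; trial displacements at `DT = 1` give the peak distance; with
#' adaptive stepping the realised `DT` is [adaptive_dt()], otherwise 1;
#' all positions are then updated simultaneously and a merge pass applied.
#' With adaptive stepping no agent ever moves more than CR in one
#' iteration, and the agent that moves farthest moves exactly CR.
#'
#' @param pop An [fvm_population()].
#' @param params An [fvm_params()] object.
#' @param adaptive Use adaptive time stepping (default `TRUE`).
#' @param iteration Iteration number stamped into the returned record.
#' @param elapsed_time Elapsed time before this step.
#' @return A list with `population` (post-step, post-merge), `record`
#'   (one-row data frame of per-iteration observables), and `equilibrium`
#'   (`TRUE` when no agent would move, in which case the population is
#'   returned unchanged and `record` is `NULL`).
#' @export
fvm_step <- function(pop, params, adaptive = TRUE, iteration = 1L,
                     elapsed_time = 0) {
  n <- n_agents(pop)
  d <- params$dimension
  forces <- matrix(0, n, d)
  sum_att <- sum_rep <- 0
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        ai <- list(position = pop$positions[i, ],
                   active_mass = pop$active_mass[i])
        aj <- list(position = pop$positions[j, ],
                   active_mass = pop$active_mass[j])
        f_on_j <- pair_force(ai, aj, params)
        f_on_i <- pair_force(aj, ai, params)
        forces[j, ] <- forces[j, ] + f_on_j$force_on_b
        forces[i, ] <- forces[i, ] + f_on_i$force_on_b
        for (pf in list(f_on_j, f_on_i)) {
          mag <- sqrt(sum(pf$force_on_b^2))
          if (pf$sign == "attractive") sum_att <- sum_att + mag
          if (pf$sign == "repulsive") sum_rep <- sum_rep + mag
        }
      }
    }
  }
  trial <- forces / pop$passive_mass
  trial_norm <- sqrt(rowSums(trial^2))
  peak <- max(trial_norm, 0)
  if (peak < 1e-12) {
    return(list(population = pop, record = NULL, equilibrium = TRUE))
  }
  dt <- if (adaptive) adaptive_dt(peak, params$coalescence_radius) else 1
  new_pos <- pop$positions + trial * dt^2
  moved <- fvm_population(new_pos, pop$active_mass, pop$passive_mass,
                          ids = pop$ids, members = pop$members)
  merged <- merge_pass(moved, params)
  total <- sum_att + sum_rep
  record <- data.frame(
    iteration = as.integer(iteration),
    dt = dt,
    elapsed_time = elapsed_time + dt,
    peak_distance = peak,
    sum_attractive = sum_att,
    sum_repulsive = sum_rep,
    repulsive_pct = if (total > 0) 100 * sum_rep / total else 0,
    n_agents = n_agents(merged),
    n_groups = sum(is_group(merged)),
    max_force = max(sqrt(rowSums(forces^2))))
  list(population = merged, record = record, equilibrium = FALSE)
}

#' Decide whether a run should stop
#'
#' Checked after every iteration. Reasons, in priority order: every pair
#' of agents is separated by more than the AIB (no interaction is
#' possible); equilibrium (the last peak trial displacement is below the
#' `1e-12` tolerance — includes a lone surviving agent); `tickstop`
#' iterations reached; at most `agent_stop` agents remain; the computed
#' `DT` exceeded `dt_stop`.
#'
#' @param pop The current [fvm_population()].
#' @param records Data frame of step records so far (the last row is
#'   inspected for `peak_distance`, `dt` and `iteration`).
#' @param stop An [fvm_stop()] object.
#' @param params An [fvm_params()] object.
#' @return A stop reason string, or `NULL` to continue.
#' @export
check_termination <- function(pop, records, stop, params) {
  n <- n_agents(pop)
  if (n >= 2L) {
    min_d <- Inf
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        min_d <- min(min_d, attribute_distance(pop$positions[i, ],
                                               pop$positions[j, ], params))
      }
    }
    if (min_d > params$aib) return("all_beyond_aib")
  }
  last <- if (NROW(records)) records[nrow(records), ] else NULL
  if (n == 1L) return("equilibrium")
  if (!is.null(last) && last$peak_distance < 1e-12) return("equilibrium")
  if (!is.null(last)) {
    if (stop$tickstop > 0L && last$iteration >= stop$tickstop)
      return("tickstop")
  }
  if (stop$agent_stop > 0L && n <= stop$agent_stop) return("agent_stop")
  if (!is.null(last) && stop$dt_stop > 0 && last$dt > stop$dt_stop)
    return("dt_stop")
  NULL
}

#' Run a full simulation
#'
#' Builds the initial population from the configuration's init spec
#' (seeding the RNG from the config seed; seed 0 draws a fresh seed and
#' records it), applies one merge pass at time zero to resolve coincident
#' or injected agents, then iterates the simulation loop in compiled code
#' until a termination condition fires. The evolution is deterministic:
#' the same configuration and seed give bit-identical results on the same
#' build.
#'
#' @param config An [fvm_config()] object.
#' @return An object of class `fvm_run` with elements:
#'   `final_population` (an [fvm_population()]), `initial_population`,
#'   `stop_reason` (one of `"equilibrium"`, `"all_beyond_aib"`,
#'   `"tickstop"`, `"agent_stop"`, `"dt_stop"`, or `"max_iterations"` if
#'   the internal safety cap of two million iterations was hit),
#'   `records` (data frame, one row per iteration), `elapsed_time`,
#'   `iterations`, `seed` (the seed actually used), `config_echo`, and
#'   `trajectory` (`NULL` unless `config$record_trajectory`).
#' @examples
#' run <- fvm_run(standard_conditions(aib = 30, seed = 1))
#' run$stop_reason
#' n_agents(run$final_population)
#' @export
fvm_run <- function(config) {
  stopifnot(inherits(config, "fvm_config"))
  seed <- config$init$seed
  if (seed == 0L) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  pop <- build_population(config$init, config$model)
  pop <- merge_pass(pop, config$model)
  p <- config$model
  res <- engine_run(pop$positions, pop$active_mass, pop$passive_mass,
                    pop$ids, pop$members,
                    p$g, p$metric_weights, p$distance_exponent,
                    p$aib, p$coalescence_radius,
                    .force_mode_code(p$force_mode),
                    isTRUE(config$adaptive),
                    config$stop$tickstop, config$stop$agent_stop,
                    config$stop$dt_stop,
                    1e-12, isTRUE(config$record_trajectory), 2000000L)
  final <- fvm_population(res$positions, res$active_mass, res$passive_mass,
                          ids = res$ids, members = res$members)
  records <- as.data.frame(res$records)
  records$iteration <- as.integer(records$iteration)
  records$n_agents <- as.integer(records$n_agents)
  records$n_groups <- as.integer(records$n_groups)
  cfg <- config
  cfg$init$seed <- seed
  structure(list(final_population = final,
                 initial_population = pop,
                 stop_reason = res$stop_reason,
                 records = records,
                 elapsed_time = res$elapsed_time,
                 iterations = res$iterations,
                 seed = seed,
                 config_echo = cfg,
                 trajectory = res$trajectory),
            class = "fvm_run")
}

#' @export
print.fvm_run <- function(x, ...) {
  cat(sprintf(paste0("<fvm_run> seed %d: %d -> %d agents (%d groups) in %d",
                     " iterations\n"),
              x$seed, n_agents(x$initial_population),
              n_agents(x$final_population), sum(is_group(x$final_population)),
              x$iterations))
  cat(sprintf("  elapsed time %.4g, stopped: %s\n", x$elapsed_time,
              x$stop_reason))
  invisible(x)
}

#' Locate a trajectory snapshot at a fraction of the elapsed time
#'
#' For a run recorded with `record_trajectory = TRUE`, returns the stored
#' population at the first iteration whose elapsed time reaches
#' `fraction` times the final elapsed time (so intermediate states can be
#' inspected without re-running).
#'
#' @param run An `fvm_run` with a stored trajectory.
#' @param fraction Fraction of the final elapsed time, in (0, 1\].
#' @return An [fvm_population()] plus attributes `iteration` and
#'   `elapsed_time`.
#' @export
snapshot_at <- function(run, fraction) {
  if (is.null(run$trajectory))
    stop("run was not recorded with `record_trajectory = TRUE`",
         call. = FALSE)
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  idx <- which(run$records$elapsed_time >= fraction * run$elapsed_time)[1L]
  snap <- run$trajectory[[idx]]
  pop <- fvm_population(snap$positions, snap$active_mass, snap$passive_mass,
                        ids = snap$ids, members = snap$members)
  attr(pop, "iteration") <- run$records$iteration[idx]
  attr(pop, "elapsed_time") <- run$records$elapsed_time[idx]
  pop
}
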