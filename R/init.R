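#' Distribution specifications for initial conditions
#'
#' Small helpers describing the per-axis spatial distributions and the
#' mass distribution of an initial population. Spatial draws falling
#' outside the visible window are rejected and redrawn; mass draws above
#' the configured maximum (or non-positive) likewise.
#'
#' @param mean,sd Mean and standard deviation of a normal distribution
#'   (`sd = 0` is the degenerate point mass at `mean`).
#' @param rate Rate of an exponential distribution.
#' @param offset Origin offset for the spatial exponential; by default the
#'   lower edge of the visible window, so the distribution is one-sided
#'   from that edge.
#' @return A distribution spec (a classed list) accepted by [fvm_init()].
#' @name dist_spec
NULL

#' @rdname dist_spec
#' @export
dist_uniform <- function() structure(list(kind = "uniform"),
                                     class = "fvm_dist")

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  if (sd < 0) stop("`sd` must be >= 0", call. = FALSE)
  structure(list(kind = "normal", mean = mean, sd = sd), class = "fvm_dist")
}

#' @rdname dist_spec
#' @export
dist_exponential <- function(rate, offset = NULL) {
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  structure(list(kind = "exponential", rate = rate, offset = offset),
            class = "fvm_dist")
}

#' Initial-condition specification
#'
#' Describes how an initial population is generated: how many agents,
#' the per-axis spatial distributions, the mass distribution and cap,
#' whether active and passive masses are tied, the RNG seed, any manually
#' injected agents, and an optional exact geometric arrangement that
#' replaces the random positions.
#'
#' @param n_agents Number of agents (>= 1).
#' @param spatial A single [dist_spec] recycled over all axes, or a list
#'   of one spec per axis.
#' @param mass A [dist_spec] for the masses.
#' @param max_mass Cap on sampled masses; draws above it are rejected and
#'   redrawn.
#' @param equal_masses If `TRUE` (default) each agent's passive mass
#'   equals its active mass; otherwise passive masses are drawn
#'   independently from the same distribution.
#' @param seed Integer RNG seed; 0 means draw a fresh seed at run time
#'   and record it.
#' @param injections List of manually placed agents, each a list with
#'   `position`, `active_mass`, `passive_mass`.
#' @param geometry Optional exact arrangement from [geometry_preset()]
#'   (a position matrix); when given it overrides `n_agents` and
#'   `spatial`, while masses are still sampled.
#' @return An object of class `fvm_init`.
#' @export
fvm_init <- function(n_agents = 100L,
                     spatial = dist_normal(0, 30),
                     mass = dist_normal(60, 15),
                     max_mass = 120,
                     equal_masses = TRUE,
                     seed = 0L,
                     injections = list(),
                     geometry = NULL) {
  if (n_agents < 1L) stop("`n_agents` must be >= 1", call. = FALSE)
  if (max_mass <= 0) stop("`max_mass` must be positive", call. = FALSE)
  if (inherits(spatial, "fvm_dist")) spatial <- list(spatial)
  if (!all(vapply(spatial, inherits, TRUE, "fvm_dist")))
    stop("`spatial` must be dist_*() specs", call. = FALSE)
  if (!inherits(mass, "fvm_dist"))
    stop("`mass` must be a dist_*() spec", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 spatial = spatial,
                 mass = mass,
                 max_mass = max_mass,
                 equal_masses = isTRUE(equal_masses),
                 seed = as.integer(seed),
                 injections = injections,
                 geometry = geometry),
            class = "fvm_init")
}

# rejection-sample one value; budget guards against specs whose support
# misses the acceptance region entirely
.sample_until <- function(draw, accept, budget = 1e6) {
  for (i in seq_len(budget)) {
    x <- draw()
    if (accept(x)) return(list(value = x, rejected = i - 1L))
  }
  stop("rejection sampling failed: no draw accepted within the retry budget",
       call. = FALSE)
}

.draw_axis <- function(spec, half_width) {
  switch(spec$kind,
    uniform = function() stats::runif(1, -half_width, half_width),
    normal = function() stats::rnorm(1, spec$mean, spec$sd),
    exponential = {
      off <- if (is.null(spec$offset)) -half_width else spec$offset
      function() off + stats::rexp(1, spec$rate)
    },
    stop("unknown spatial distribution: ", spec$kind, call. = FALSE))
}

#' Sample initial positions with rejection
#'
#' Draws `n_agents` positions agent by agent (x first, then y, ...), each
#' axis from its own distribution. A coordinate outside the visible window
#' is rejected and redrawn; the total number of discarded draws is
#' reported. Uses the current RNG state ([fvm_run()] seeds it from the
#' config).
#'
#' @param init An [fvm_init()] spec.
#' @param params An [fvm_params()] object (dimension, visible window).
#' @return A list with `positions` (matrix, all coordinates within the
#'   window) and `rejected_count`.
#' @export
sample_positions <- function(init, params) {
  d <- params$dimension
  hw <- params$visible_half_width
  specs <- init$spatial
  if (length(specs) == 1L) specs <- rep(specs, d)
  if (length(specs) != d)
    stop("`spatial` must supply one distribution per axis", call. = FALSE)
  draws <- lapply(specs, .draw_axis, half_width = hw)
  inside <- function(x) x >= -hw && x <= hw
  pos <- matrix(0, init$n_agents, d)
  rejected <- 0L
  for (i in seq_len(init$n_agents)) {
    for (k in seq_len(d)) {
      s <- .sample_until(draws[[k]], inside)
      pos[i, k] <- s$value
      rejected <- rejected + s$rejected
    }
  }
  list(positions = pos, rejected_count = rejected)
}

#' Sample agent masses with rejection
#'
#' Draws one active mass per agent from the configured distribution,
#' rejecting draws above `max_mass` or non-positive ones. With
#' `equal_masses` the passive masses equal the active masses; otherwise
#' they are drawn independently from the same distribution.
#'
#' @inheritParams sample_positions
#' @return A list with `active` and `passive` numeric vectors.
#' @export
sample_masses <- function(init, params) {
  spec <- init$mass
  draw <- switch(spec$kind,
    uniform = function() stats::runif(1, 0, init$max_mass),
    normal = function() stats::rnorm(1, spec$mean, spec$sd),
    exponential = function() stats::rexp(1, spec$rate),
    stop("unknown mass distribution: ", spec$kind, call. = FALSE))
  ok <- function(x) x > 0 && x <= init$max_mass
  active <- vapply(seq_len(init$n_agents),
                   function(i) .sample_until(draw, ok)$value, numeric(1))
  passive <- if (init$equal_masses) active else
    vapply(seq_len(init$n_agents),
           function(i) .sample_until(draw, ok)$value, numeric(1))
  list(active = active, passive = passive)
}

#' Exact symmetric arrangements
#'
#' Regular arrangements used to probe the model's symmetries: a square
#' (4 points at the circumradius, at 45/135/225/315 degrees plus an
#' optional rotation), an equilateral triangle (90/210/330 degrees), or a
#' ring of `k` equally spaced points.
#'
#' @param kind `"square"`, `"triangle"` or `"ring"`.
#' @param circumradius Distance of every point from the origin.
#' @param k Number of points on a ring (>= 2).
#' @param rotation Rotation of the whole arrangement, degrees
#'   counterclockwise.
#' @return A position matrix suitable for `fvm_init(geometry = ...)`.
#' @examples
#' geometry_preset("square", circumradius = sqrt(2))  # corners (+-1, +-1)
#' @export
geometry_preset <- function(kind = c("square", "triangle", "ring"),
                            circumradius, k = NULL, rotation = 0) {
  kind <- match.arg(kind)
  if (circumradius <= 0) stop("`circumradius` must be positive", call. = FALSE)
  angles <- switch(kind,
    square = c(45, 135, 225, 315),
    triangle = c(90, 210, 330),
    ring = {
      if (is.null(k) || k < 2L) stop("ring needs `k` >= 2", call. = FALSE)
      360 * (seq_len(k) - 1L) / k
    })
  theta <- (angles + rotation) * pi / 180
  circumradius * cbind(cos(theta), sin(theta))
}

#' Add a manually placed agent to a population
#'
#' Appends one agent with a fresh id (one above the largest member id in
#' the population). An agent injected exactly at the origin has a null
#' attribute vector and neither exerts nor receives any force while it
#' stays there; two agents injected at the same point are merged by the
#' time-zero merge pass of [fvm_run()].
#'
#' @param pop An [fvm_population()].
#' @param position Attribute vector for the new agent.
#' @param active_mass,passive_mass Positive masses.
#' @return The extended population.
#' @export
inject_agent <- function(pop, position, active_mass, passive_mass) {
  if (active_mass <= 0 || passive_mass <= 0)
    stop("masses must be positive", call. = FALSE)
  if (length(position) != ncol(pop$positions))
    stop("`position` has the wrong dimension", call. = FALSE)
  new_id <- max(unlist(pop$members)) + 1L
  fvm_population(rbind(pop$positions, position),
                 c(pop$active_mass, active_mass),
                 c(pop$passive_mass, passive_mass),
                 ids = c(pop$ids, new_id),
                 members = c(pop$members, list(new_id)))
}

#' Build the initial population for a run
#'
#' Realises an [fvm_init()] spec into an [fvm_population()]: positions
#' come from the geometry preset when one is given, otherwise from
#' [sample_positions()]; masses from [sample_masses()]; injected agents
#' are appended last. Uses the current RNG state.
#'
#' @inheritParams sample_positions
#' @return An [fvm_population()] with attribute `rejected_count`.
#' @export
build_population <- function(init, params) {
  if (!is.null(init$geometry)) {
    pos <- as.matrix(init$geometry)
    if (ncol(pos) != params$dimension)
      stop("geometry dimension does not match `params$dimension`",
           call. = FALSE)
    init$n_agents <- nrow(pos)
    rejected <- 0L
  } else {
    s <- sample_positions(init, params)
    pos <- s$positions
    rejected <- s$rejected_count
  }
  m <- sample_masses(init, params)
  pop <- fvm_population(pos, m$active, m$passive)
  for (inj in init$injections) {
    pop <- inject_agent(pop, inj$position, inj$active_mass, inj$passive_mass)
  }
  attr(pop, "rejected_count") <- rejected
  pop
}

#' Standard Conditions configuration
#'
#' The baseline configuration used throughout the package's experiments:
#' 100 agents, positions normal with mean 0 and SD 30 on each axis
#' (rejected outside the visible window), masses normal with mean 60 and
#' SD 15 capped at 120, passive mass equal to active mass, `g = 7e-5`,
#' inverse-square force law, `CR = 0.2`, adaptive time stepping on. The
#' Attribute Influence Bound must be chosen per experiment.
#'
#' @param aib Attribute Influence Bound for this run.
#' @param seed RNG seed (0 = fresh).
#' @param center Center of the spatial distribution, default the origin;
#'   a scalar is recycled over all axes (the consensus experiments move
#'   it around).
#' @param ... Further arguments passed to [fvm_config()] (e.g. `stop`,
#'   `record_trajectory`) or to override model parameters (`g`,
#'   `coalescence_radius`, `distance_exponent`, `force_mode`,
#'   `dimension`).
#' @return An [fvm_config()] object.
#' @examples
#' cfg <- standard_conditions(aib = 100, seed = 61)
#' @export
standard_conditions <- function(aib, seed = 0L, center = 0, ...) {
  dots <- list(...)
  par_names <- intersect(names(dots),
                         c("g", "coalescence_radius", "distance_exponent",
                           "force_mode", "dimension", "metric_weights",
                           "visible_half_width"))
  model <- do.call(fvm_params, c(list(aib = aib), dots[par_names]))
  d <- model$dimension
  if (length(center) == 1L) center <- rep(center, d)
  if (length(center) != d)
    stop("`center` must have one value per dimension", call. = FALSE)
  init <- fvm_init(n_agents = 100L,
                   spatial = lapply(center, function(mu) dist_normal(mu, 30)),
                   mass = dist_normal(60, 15),
                   max_mass = 120,
                   equal_masses = TRUE,
                   seed = seed)
  rest <- dots[setdiff(names(dots), par_names)]
  do.call(fvm_config, c(list(model = model, init = init), rest))
}
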