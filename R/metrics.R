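#' Center of attributes
#'
#' Active-mass-weighted mean attribute vector of the population, the
#' analogue of a center of mass. It moves very little during a run with
#' origin-centered initial conditions, which makes it a useful
#' conservation check.
#'
#' @param pop An [fvm_population()].
#' @return Numeric vector of length `d`.
#' @examples
#' pop <- fvm_population(rbind(c(10, 0), c(40, 0)), c(60, 120), c(60, 120))
#' center_of_attributes(pop)  # (30, 0)
#' @export
center_of_attributes <- function(pop) {
  colSums(pop$positions * pop$active_mass) / sum(pop$active_mass)
}

# full matrix of metric-weighted pairwise distances
.pairwise_distances <- function(pop, params) {
  w <- params$metric_weights
  x <- sweep(pop$positions, 2L, sqrt(w), `*`)
  as.matrix(stats::dist(x))
}

#' Mean distance to the closest neighbor (MDCN)
#'
#' Mean, over agents, of the attribute distance to the nearest other
#' agent. At the end of large-AIB runs the MDCN approaches the AIB itself:
#' the few surviving groups repel each other until they just lose contact.
#'
#' @param pop An [fvm_population()] with at least 2 agents.
#' @param params An [fvm_params()] object.
#' @return Non-negative scalar.
#' @export
mdcn <- function(pop, params) {
  n <- n_agents(pop)
  if (n < 2L)
    stop("MDCN is undefined for fewer than 2 agents", call. = FALSE)
  dm <- .pairwise_distances(pop, params)
  diag(dm) <- Inf
  mean(apply(dm, 1L, min))
}

#' Mean pairwise distance
#'
#' Mean attribute distance over all unordered pairs of live agents.
#'
#' @inheritParams mdcn
#' @return Non-negative scalar.
#' @export
mean_pairwise_distance <- function(pop, params) {
  n <- n_agents(pop)
  if (n < 2L)
    stop("mean pairwise distance is undefined for fewer than 2 agents",
         call. = FALSE)
  dm <- .pairwise_distances(pop, params)
  mean(dm[upper.tri(dm)])
}

#' Mean distance of agents to the origin
#' @inheritParams mdcn
#' @return Non-negative scalar (plain Euclidean norm of each position).
#' @export
mean_origin_distance <- function(pop, params = NULL) {
  mean(sqrt(rowSums(pop$positions^2)))
}

# polar angles in [0, 360), d = 2 only; origin agents dropped
.polar_angles <- function(pop) {
  if (ncol(pop$positions) != 2L)
    stop("angular metrics are defined for dimension 2 only", call. = FALSE)
  r <- sqrt(rowSums(pop$positions^2))
  at_origin <- r == 0
  ang <- atan2(pop$positions[!at_origin, 2L],
               pop$positions[!at_origin, 1L]) * 180 / pi
  list(angles = ang %% 360, n_at_origin = sum(at_origin))
}

#' Angular sector histogram
#'
#' Bins the polar angles of the agents into `n_sectors` equal sectors
#' (sector 1 spans \[0, 360/n) degrees counterclockwise from the +x axis;
#' half-open bins) and normalises so that a uniform angular distribution
#' gives 1.0 per sector in expectation. Agents at the exact origin have no
#' angle and are excluded (their count is reported as an attribute).
#'
#' @param pop An [fvm_population()] in dimension 2.
#' @param n_sectors Number of sectors (default 12, i.e. 30-degree bins).
#' @return Numeric vector of normalised sector counts with attribute
#'   `n_at_origin`; the values average exactly 1 whenever any agent is
#'   binned.
#' @export
sector_histogram <- function(pop, n_sectors = 12L) {
  pa <- .polar_angles(pop)
  sect <- floor(pa$angles / (360 / n_sectors)) + 1L
  counts <- tabulate(sect, nbins = n_sectors)
  total <- sum(counts)
  out <- if (total > 0) counts / (total / n_sectors) else rep(0, n_sectors)
  attr(out, "n_at_origin") <- pa$n_at_origin
  out
}

#' Angles between adjacent agents
#'
#' Sorts the agents by polar angle and returns the consecutive
#' differences, including the wrap-around gap, so the gaps always sum to
#' 360 degrees. Agents at the exact origin are excluded with a warning.
#'
#' @param pop An [fvm_population()] in dimension 2 with at least 2 agents
#'   off the origin.
#' @return Numeric vector of gaps in degrees (one per agent).
#' @examples
#' tri <- fvm_population(geometry_preset("triangle", 50), rep(60, 3),
#'                       rep(60, 3))
#' adjacent_angle_gaps(tri)  # 120 120 120
#' @export
adjacent_angle_gaps <- function(pop) {
  pa <- .polar_angles(pop)
  if (pa$n_at_origin > 0)
    warning(pa$n_at_origin,
            " agent(s) at the exact origin excluded from angle gaps")
  ang <- sort(pa$angles)
  if (length(ang) < 2L)
    stop("angle gaps need at least 2 agents off the origin", call. = FALSE)
  c(diff(ang), 360 - (ang[length(ang)] - ang[1L]))
}

#' Decompose total force into attractive and repulsive parts
#'
#' Sums the magnitudes of the directed pairwise forces over all
#' communicating pairs (both directions of each unordered pair, since the
#' force law is asymmetric in the masses), split by sign: attractive
#' (positive dot product under the NORMAL mode) versus repulsive. The
#' repulsive percentage is `100 * rep / (att + rep)`, or 0 when no force
#' acts.
#'
#' @inheritParams mdcn
#' @return A list with `sum_attractive`, `sum_repulsive` and
#'   `repulsive_pct`.
#' @export
force_decomposition <- function(pop, params) {
  n <- n_agents(pop)
  sum_att <- sum_rep <- 0
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        for (ord in list(c(i, j), c(j, i))) {
          a <- list(position = pop$positions[ord[1L], ],
                    active_mass = pop$active_mass[ord[1L]])
          b <- list(position = pop$positions[ord[2L], ])
          pf <- pair_force(a, b, params)
          mag <- sqrt(sum(pf$force_on_b^2))
          if (pf$sign == "attractive") sum_att <- sum_att + mag
          if (pf$sign == "repulsive") sum_rep <- sum_rep + mag
        }
      }
    }
  }
  total <- sum_att + sum_rep
  list(sum_attractive = sum_att, sum_repulsive = sum_rep,
       repulsive_pct = if (total > 0) 100 * sum_rep / total else 0)
}

#' Moment of inertia about the origin
#'
#' `sum_i M_i |r_i|^2` with passive (inertial) masses, about the origin of
#' attribute space.
#'
#' @param pop An [fvm_population()].
#' @return Non-negative scalar.
#' @export
moment_of_inertia <- function(pop) {
  sum(pop$passive_mass * rowSums(pop$positions^2))
}

#' All monitored observables for one population
#'
#' Convenience wrapper computing every monitored quantity at once:
#' center of attributes, MDCN, mean pairwise distance, mean distance to
#' the origin, the 12-sector angular histogram, annular and mass
#' histograms, moment of inertia, and the force decomposition.
#' Pair-based metrics are `NA` for a single agent; angular metrics are
#' only computed in dimension 2.
#'
#' @inheritParams mdcn
#' @param annular_bin,mass_bin Bin widths (model units / mass units) for
#'   the annular and mass histograms.
#' @return A list of class `fvm_metrics`.
#' @export
metrics_snapshot <- function(pop, params, annular_bin = 5, mass_bin = 10) {
  n <- n_agents(pop)
  r <- sqrt(rowSums(pop$positions^2))
  fd <- force_decomposition(pop, params)
  structure(list(
    center_of_attributes = center_of_attributes(pop),
    mdcn = if (n >= 2L) mdcn(pop, params) else NA_real_,
    mean_pairwise = if (n >= 2L) mean_pairwise_distance(pop, params)
                    else NA_real_,
    mean_dist_origin = mean_origin_distance(pop),
    sector_hist = if (ncol(pop$positions) == 2L) sector_histogram(pop)
                  else NULL,
    annular_hist = table(cut(r, breaks = seq(0, max(r) + annular_bin,
                                             by = annular_bin),
                             right = FALSE)),
    mass_hist = table(cut(pop$active_mass,
                          breaks = seq(0, max(pop$active_mass) + mass_bin,
                                       by = mass_bin),
                          right = FALSE)),
    moment_of_inertia = moment_of_inertia(pop),
    sum_attractive = fd$sum_attractive,
    sum_repulsive = fd$sum_repulsive,
    repulsive_pct = fd$repulsive_pct,
    n_agents = n,
    n_groups = sum(is_group(pop))), class = "fvm_metrics")
}
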