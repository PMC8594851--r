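#' Metric-weighted attribute distance
#'
#' Distance between two attribute vectors,
#' `sqrt(sum_k w_k (a_k - b_k)^2)`, with per-axis metric weights `w_k`.
#' With unit weights this is the ordinary Euclidean distance in attribute
#' space; unequal weights let different attributes count differently.
#'
#' @param pos_a,pos_b Numeric attribute vectors of length
#'   `params$dimension`.
#' @param params An [fvm_params()] object.
#' @return Non-negative scalar distance; zero iff the positions coincide.
#' @examples
#' attribute_distance(c(3, 0), c(0, 4), fvm_params())  # 5
#' @export
attribute_distance <- function(pos_a, pos_b, params) {
  if (length(pos_a) != params$dimension || length(pos_b) != params$dimension)
    stop("attribute vectors must have dimension ", params$dimension,
         call. = FALSE)
  diff <- pos_a - pos_b
  sqrt(sum(params$metric_weights * diff * diff))
}

#' Pairwise force between two agents
#'
#' The force of agent A on agent B is
#' `g * m_A * (A . B) / R^p * (A - B) / R`, where `m_A` is A's active
#' mass, `A . B` the dot product of the two attribute vectors, `R` the
#' metric-weighted attribute distance and `p` the distance exponent. The
#' sign of the dot product makes the force attractive (agents pointing the
#' same general way, angle < 90 degrees), zero (orthogonal), or repulsive
#' (angle > 90 degrees). When `R` exceeds the Attribute Influence Bound
#' the agents are forbidden to interact and the force is zero
#' (`sign = "blocked"`). The direction vector uses the unweighted
#' difference `A - B` normalised by the weighted `R`; for unit weights
#' this is the ordinary unit vector.
#'
#' Force modes post-process the scalar prefactor: `ATTRACT_ONLY` takes its
#' absolute value, `REPEL_ONLY` minus the absolute value,
#' `ZERO_REPULSIVE` zeroes negative-dot pairs, `ZERO_ATTRACTIVE` zeroes
#' positive-dot pairs, `INVERT` flips the sign.
#'
#' Coincident agents with distinct ids (`R = 0`) are flagged degenerate:
#' the force is undefined there, returned as zero with `sign = "zero"`,
#' and the caller is expected to merge them.
#'
#' @param a,b Single-agent slices: lists with `position` (numeric vector)
#'   and for `a` an `active_mass`; any object with those names works, e.g.
#'   `list(position = c(10, 0), active_mass = 60)`.
#' @param params An [fvm_params()] object.
#' @return A list of class `fvm_pair` with `r_vec` (A - B), `r_mag`,
#'   `dot`, `omega` (angle between the vectors, degrees, `NA` when either
#'   vector is null), `force_on_b`, and
#'   `sign` in `c("attractive", "repulsive", "zero", "blocked")`.
#' @examples
#' p <- fvm_params()
#' a <- list(position = c(10, 0), active_mass = 60)
#' b <- list(position = c(20, 0), active_mass = 60)
#' pair_force(a, b, p)$force_on_b  # (-0.0084, 0): B pulled toward A
#' @export
pair_force <- function(a, b, params) {
  A <- as.numeric(a$position)
  B <- as.numeric(b$position)
  r_vec <- A - B
  r_mag <- attribute_distance(A, B, params)
  dot <- sum(A * B)
  na <- sqrt(sum(A * A))
  nb <- sqrt(sum(B * B))
  omega <- if (na == 0 || nb == 0) NA_real_ else {
    cosw <- max(-1, min(1, dot / (na * nb)))
    acos(cosw) * 180 / pi
  }
  zero <- rep(0, length(A))
  if (r_mag > params$aib) {
    return(structure(list(r_vec = r_vec, r_mag = r_mag, dot = dot,
                          omega = omega, force_on_b = zero,
                          sign = "blocked"), class = "fvm_pair"))
  }
  if (r_mag == 0) {
    # degenerate coincident pair: caller must merge
    return(structure(list(r_vec = r_vec, r_mag = r_mag, dot = dot,
                          omega = omega, force_on_b = zero,
                          sign = "zero"), class = "fvm_pair"))
  }
  scalar <- params$g * a$active_mass * dot / r_mag^params$distance_exponent
  scalar <- switch(params$force_mode,
    NORMAL = scalar,
    ATTRACT_ONLY = abs(scalar),
    REPEL_ONLY = -abs(scalar),
    ZERO_REPULSIVE = if (dot < 0) 0 else scalar,
    ZERO_ATTRACTIVE = if (dot > 0) 0 else scalar,
    INVERT = -scalar)
  sign <- if (scalar > 0) "attractive" else if (scalar < 0) "repulsive" else "zero"
  structure(list(r_vec = r_vec, r_mag = r_mag, dot = dot, omega = omega,
                 force_on_b = scalar * r_vec / r_mag, sign = sign),
            class = "fvm_pair")
}

#' Net force on one agent from the whole population
#'
#' Vector sum of the pairwise forces exerted on the indexed agent by every
#' other live agent within the Attribute Influence Bound. A population of
#' one feels no force.
#'
#' @param index Row index of the agent receiving the force.
#' @param pop An [fvm_population()].
#' @param params An [fvm_params()] object.
#' @return Numeric force vector of length `params$dimension`.
#' @export
net_force <- function(index, pop, params) {
  n <- n_agents(pop)
  if (index < 1L || index > n) stop("`index` out of range", call. = FALSE)
  total <- rep(0, params$dimension)
  b <- list(position = pop$positions[index, ])
  for (j in seq_len(n)) {
    if (j == index) next
    a <- list(position = pop$positions[j, ], active_mass = pop$active_mass[j])
    total <- total + pair_force(a, b, params)$force_on_b
  }
  total
}

#' Displacement of an agent under a force
#'
#' Integrating Newton's law with a constant acceleration `F / M` over a
#' time interval `dt` gives the attribute increment `(F / M) * dt^2`
#' (the model's convention; no factor 1/2). Linear in the force, quadratic
#' in the time step.
#'
#' @param force Numeric force vector.
#' @param passive_mass Positive scalar passive (inertial) mass.
#' @param dt Positive time interval.
#' @return Numeric increment to add to the agent's attribute vector.
#' @examples
#' displacement(c(-0.0084, 0), 60, 1)  # (-1.4e-4, 0)
#' @export
displacement <- function(force, passive_mass, dt) {
  if (!is.numeric(passive_mass) || length(passive_mass) != 1L ||
      passive_mass <= 0)
    stop("`passive_mass` must be a positive scalar", call. = FALSE)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  force / passive_mass * dt^2
}
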