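#' Force-law parameters
#'
#' Bundles the constants of the force vector model: the global force scale
#' `g`, the per-axis metric weights used in the attribute distance, the
#' distance exponent, the Attribute Influence Bound (AIB) beyond which two
#' agents cannot interact, the Coalescence Radius (CR) below which agents
#' merge into a permanent group, the force mode, and the dimensionality of
#' attribute space.
#'
#' @param g Positive force-scaling constant. The default `7e-5` gives
#'   perceptible motion per unit time step; with adaptive time stepping the
#'   trajectories are independent of `g` (only elapsed time rescales).
#' @param metric_weights Vector of `dimension` positive weights applied
#'   per axis inside the attribute distance. Default all 1 (plain Euclidean
#'   distance).
#' @param distance_exponent Positive exponent `p` of the separation in the
#'   force denominator; default 2 (inverse-square law).
#' @param aib Attribute Influence Bound: maximum attribute distance over
#'   which two agents exert any force on one another. Default 280, the
#'   diagonal of the visible window.
#' @param coalescence_radius Distance below which agents merge; also the
#'   cap on any per-iteration displacement under adaptive time stepping.
#'   Must be smaller than `aib`. Default 0.2.
#' @param force_mode One of `"NORMAL"`, `"ATTRACT_ONLY"`, `"REPEL_ONLY"`,
#'   `"ZERO_REPULSIVE"`, `"ZERO_ATTRACTIVE"`, `"INVERT"`. `NORMAL` lets the
#'   dot product set the sign; `ATTRACT_ONLY` takes the absolute value of
#'   the scalar prefactor, `REPEL_ONLY` minus the absolute value,
#'   `ZERO_REPULSIVE`/`ZERO_ATTRACTIVE` zero out one sign class, and
#'   `INVERT` flips the sign.
#' @param dimension Integer dimension `d >= 2` of attribute space
#'   (default 2).
#' @param visible_half_width Half-width of the visible window per axis
#'   (default 100, i.e. the \[-100, 100\] square). Positions are never
#'   clamped to it; agents outside are "ghosts" that keep interacting.
#'
#' @return An object of class `fvm_params`.
#' @examples
#' p <- fvm_params(aib = 100)
#' p$coalescence_radius
#' @export
fvm_params <- function(g = 7e-5,
                       metric_weights = rep(1, dimension),
                       distance_exponent = 2,
                       aib = 280,
                       coalescence_radius = 0.2,
                       force_mode = c("NORMAL", "ATTRACT_ONLY", "REPEL_ONLY",
                                      "ZERO_REPULSIVE", "ZERO_ATTRACTIVE",
                                      "INVERT"),
                       dimension = 2L,
                       visible_half_width = 100) {
  force_mode <- match.arg(force_mode)
  dimension <- as.integer(dimension)
  if (dimension < 2L)
    stop("`dimension` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("`g` must be a positive scalar", call. = FALSE)
  if (length(metric_weights) != dimension || any(metric_weights <= 0))
    stop("`metric_weights` must be ", dimension, " positive values",
         call. = FALSE)
  if (distance_exponent <= 0)
    stop("`distance_exponent` must be positive", call. = FALSE)
  if (aib <= 0) stop("`aib` must be positive", call. = FALSE)
  if (coalescence_radius <= 0)
    stop("`coalescence_radius` must be positive", call. = FALSE)
  if (coalescence_radius >= aib)
    stop("`coalescence_radius` must be smaller than `aib`", call. = FALSE)
  if (visible_half_width <= 0)
    stop("`visible_half_width` must be positive", call. = FALSE)
  structure(
    list(g = g,
         metric_weights = as.numeric(metric_weights),
         distance_exponent = distance_exponent,
         aib = aib,
         coalescence_radius = coalescence_radius,
         force_mode = force_mode,
         dimension = dimension,
         visible_half_width = visible_half_width),
    class = "fvm_params")
}

#' @export
print.fvm_params <- function(x, ...) {
  cat("<fvm_params>\n")
  cat(sprintf("  g = %g, exponent = %g, AIB = %g, CR = %g\n",
              x$g, x$distance_exponent, x$aib, x$coalescence_radius))
  cat(sprintf("  dimension = %d, metric weights = (%s), mode = %s\n",
              x$dimension, paste(format(x$metric_weights), collapse = ", "),
              x$force_mode))
  invisible(x)
}

# integer code handed to the compiled engine
.force_mode_code <- function(mode) {
  match(mode, c("NORMAL", "ATTRACT_ONLY", "REPEL_ONLY",
                "ZERO_REPULSIVE", "ZERO_ATTRACTIVE", "INVERT")) - 1L
}

#' Stop criteria for a simulation
#'
#' Any criterion set to 0 is off. A run always stops on its own when
#' equilibrium is reached (no agent moves) or when all agents are separated
#' by more than the AIB.
#'
#' @param tickstop Maximum number of iterations (0 = off).
#' @param agent_stop Stop when at most this many agents remain (0 = off).
#' @param dt_stop Stop once the computed adaptive time step exceeds this
#'   value (0 = off); a large DT means forces have become very weak.
#' @return An object of class `fvm_stop`.
#' @export
fvm_stop <- function(tickstop = 0L, agent_stop = 0L, dt_stop = 0) {
  if (tickstop < 0 || agent_stop < 0 || dt_stop < 0)
    stop("stop criteria must be >= 0 (0 = off)", call. = FALSE)
  structure(list(tickstop = as.integer(tickstop),
                 agent_stop = as.integer(agent_stop),
                 dt_stop = as.numeric(dt_stop)),
            class = "fvm_stop")
}
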