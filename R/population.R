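#' Agent populations
#'
#' A population is the live set of agents (individuals and merged groups).
#' Each agent has an attribute vector (one row of `positions`), a positive
#' active mass `m` that scales the force it exerts ("charisma"), a positive
#' passive mass `M` that divides the force it receives ("resistance"), and
#' the set of original agent ids it has absorbed. An agent with more than
#' one member is a group. Member-id sets across live agents always
#' partition the original id set, and merging only ever sums masses, so
#' total active and passive mass are conserved over a run.
#'
#' @param positions Numeric matrix, one row per agent, `d` columns.
#' @param active_mass,passive_mass Positive numeric vectors, one entry per
#'   agent.
#' @param ids Integer agent ids (default `1:n`); must be unique.
#' @param members List of integer vectors, the original ids absorbed into
#'   each agent (default: each agent is the singleton of its own id).
#'
#' @return An object of class `fvm_population`: a list with elements
#'   `ids`, `positions`, `active_mass`, `passive_mass`, `members`.
#' @examples
#' pop <- fvm_population(rbind(c(10, 0), c(0, 10)), c(60, 60), c(60, 60))
#' n_agents(pop)
#' @export
fvm_population <- function(positions, active_mass, passive_mass,
                           ids = seq_len(nrow(positions)),
                           members = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (length(active_mass) != n || length(passive_mass) != n)
    stop("mass vectors must have one entry per agent", call. = FALSE)
  if (any(active_mass <= 0) || any(passive_mass <= 0))
    stop("all masses must be positive", call. = FALSE)
  ids <- as.integer(ids)
  if (anyDuplicated(ids)) stop("agent ids must be unique", call. = FALSE)
  if (is.null(members)) members <- as.list(ids)
  members <- lapply(members, function(m) sort(as.integer(m)))
  if (length(members) != n || any(lengths(members) == 0L))
    stop("`members` must hold a non-empty id set per agent", call. = FALSE)
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    stop("member id sets must be disjoint", call. = FALSE)
  structure(list(ids = ids,
                 positions = positions,
                 active_mass = as.numeric(active_mass),
                 passive_mass = as.numeric(passive_mass),
                 members = members),
            class = "fvm_population")
}

#' Number of live agents in a population
#' @param pop An `fvm_population`.
#' @return Integer count of live agents (individuals plus groups).
#' @export
n_agents <- function(pop) nrow(pop$positions)

#' Which live agents are groups
#' @param pop An `fvm_population`.
#' @return Logical vector, `TRUE` for agents holding more than one member.
#' @export
is_group <- function(pop) lengths(pop$members) > 1L

#' @export
print.fvm_population <- function(x, ...) {
  n <- n_agents(x)
  cat(sprintf("<fvm_population> %d agents (%d groups), dimension %d\n",
              n, sum(is_group(x)), ncol(x$positions)))
  cat(sprintf("  total active mass %.6g, total passive mass %.6g\n",
              sum(x$active_mass), sum(x$passive_mass)))
  invisible(x)
}

#' @export
as.data.frame.fvm_population <- function(x, ...) {
  d <- ncol(x$positions)
  out <- data.frame(id = x$ids)
  for (k in seq_len(d)) out[[paste0("x", k)]] <- x$positions[, k]
  out$active_mass <- x$active_mass
  out$passive_mass <- x$passive_mass
  out$is_group <- is_group(x)
  out$n_members <- lengths(x$members)
  out$member_ids <- vapply(x$members, paste, "", collapse = ";")
  out
}

#' Flag agents outside the visible window
#'
#' Positions are never clamped: an agent that drifts beyond the visible
#' half-width keeps interacting fully ("ghost" agent). This helper only
#' reports which agents are currently outside, for bookkeeping.
#'
#' @param pop An `fvm_population`.
#' @param params An [fvm_params()] object (supplies the half-width).
#' @return Logical vector, `TRUE` where any coordinate exceeds the window.
#' @export
out_of_visible <- function(pop, params) {
  apply(abs(pop$positions) > params$visible_half_width, 1L, any)
}
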