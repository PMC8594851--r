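# shared fixtures: tiny populations and a rotation helper

default_params <- function(...) fvm_params(...)

# population from a position matrix with unit-simple masses
pop_at <- function(positions, active = NULL, passive = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (is.null(active)) active <- rep(60, n)
  if (is.null(passive)) passive <- active
  fvm_population(positions, active, passive)
}

rotate2 <- function(positions, degrees) {
  th <- degrees * pi / 180
  positions %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
}

# config with exact starting positions (geometry bypasses position sampling,
# so two configs sharing a seed draw identical masses)
config_with_positions <- function(positions, aib, seed = 1L, ...) {
  fvm_config(model = fvm_params(aib = aib, ...),
             init = fvm_init(n_agents = nrow(positions),
                             geometry = positions,
                             mass = dist_normal(60, 15), max_mass = 120,
                             seed = seed))
}
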