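test_that("adaptive time step follows DT^2 = CR / peak", {
  expect_equal(adaptive_dt(0.2, 0.2), 1)
  expect_equal(adaptive_dt(0.2 / 16, 0.2), 4)
  expect_error(adaptive_dt(0, 0.2), class = "fvm_equilibrium")
})

test_that("merge pass follows the greater-active-mass rule", {
  p <- default_params()
  pop <- fvm_population(rbind(c(10, 10), c(10.1, 10)), c(60, 70), c(60, 70))
  merged <- merge_pass(pop, p)
  expect_equal(n_agents(merged), 1L)
  expect_equal(merged$positions[1, ], c(10.1, 10))
  expect_equal(merged$active_mass, 130)
  expect_equal(merged$passive_mass, 130)
  expect_equal(merged$members[[1]], c(1L, 2L))
  expect_true(is_group(merged))
  # no pair within CR: unchanged
  spread <- pop_at(rbind(c(0, 0), c(5, 5), c(-9, 3)))
  expect_equal(merge_pass(spread, p)$positions, spread$positions)
})

test_that("merging is transitive within one pass (chain -> one group)", {
  p <- default_params()  # CR = 0.2
  chain <- pop_at(rbind(c(0, 0), c(0.15, 0), c(0.30, 0)))
  expect_gt(attribute_distance(chain$positions[1, ], chain$positions[3, ], p),
            p$coalescence_radius)
  merged <- merge_pass(chain, p)
  expect_equal(n_agents(merged), 1L)
  expect_equal(merged$members[[1]], 1:3)
})

test_that("merge components agree with an independent graph oracle", {
  skip_if_not_installed("igraph")
  p <- default_params()
  set.seed(3)
  for (rep in 1:10) {
    pos <- matrix(runif(30, 0, 1.2), 15, 2)
    pop <- pop_at(pos)
    merged <- merge_pass(pop, p)
    dm <- as.matrix(dist(pos))
    adj <- dm < p$coalescence_radius
    diag(adj) <- FALSE
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
      adj, mode = "undirected"))
    expect_equal(n_agents(merged), comp$no)
    got <- lapply(merged$members, identity)
    want <- unname(split(seq_len(15), comp$membership))
    expect_setequal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("ties at exactly CR do not merge; strict inequality applies", {
  p <- default_params()
  exact <- pop_at(rbind(c(0, 0), c(p$coalescence_radius, 0)))
  expect_equal(n_agents(merge_pass(exact, p)), 2L)
  inside <- pop_at(rbind(c(0, 0), c(p$coalescence_radius - 1e-9, 0)))
  expect_equal(n_agents(merge_pass(inside, p)), 1L)
})

test_that("a step detects equilibrium for an all-orthogonal population", {
  p <- default_params()
  pop <- pop_at(rbind(c(10, 0), c(0, 10)))
  out <- fvm_step(pop, p)
  expect_true(out$equilibrium)
  expect_null(out$record)
  expect_equal(out$population$positions, pop$positions)
})

test_that("a step composes pair force and displacement, capped at CR", {
  p <- fvm_params(aib = 100)
  pop <- pop_at(rbind(c(10, 0), c(20, 0)))
  out <- fvm_step(pop, p)
  expect_false(out$equilibrium)
  rec <- out$record
  # trial displacements from the worked pair forces
  f_on_2 <- pair_force(list(position = c(10, 0), active_mass = 60),
                       list(position = c(20, 0)), p)$force_on_b
  f_on_1 <- pair_force(list(position = c(20, 0), active_mass = 60),
                       list(position = c(10, 0)), p)$force_on_b
  trial <- rbind(f_on_1 / 60, f_on_2 / 60)
  expect_equal(rec$peak_distance, max(sqrt(rowSums(trial^2))))
  dt <- adaptive_dt(rec$peak_distance, p$coalescence_radius)
  expect_equal(rec$dt, dt)
  expect_equal(out$population$positions,
               pop$positions + trial * dt^2)
  # both agents moved toward each other; the larger trial move equals CR
  moved <- sqrt(rowSums((out$population$positions - pop$positions)^2))
  expect_equal(max(moved), p$coalescence_radius)
})

test_that("adaptive stepping caps every displacement at CR over a run", {
  cfg <- standard_conditions(aib = 60, seed = 5, record_trajectory = TRUE)
  run <- fvm_run(cfg)
  cr <- cfg$model$coalescence_radius
  prev <- run$initial_population
  worst <- 0
  hit_cap <- 0L
  for (snap in run$trajectory) {
    common <- intersect(prev$ids, snap$ids)
    # agents that did not merge this iteration moved by force alone;
    # merge winners may additionally jump to the heavy member's position
    same_size <- lengths(snap$members[match(common, snap$ids)]) ==
                 lengths(prev$members[match(common, prev$ids)])
    keep <- common[same_size]
    a <- prev$positions[match(keep, prev$ids), , drop = FALSE]
    b <- snap$positions[match(keep, snap$ids), , drop = FALSE]
    moved <- sqrt(rowSums((b - a)^2))
    worst <- max(worst, moved)
    if (any(abs(moved - cr) < 1e-9)) hit_cap <- hit_cap + 1L
    prev <- snap
  }
  expect_lte(worst, cr + 1e-9)
  # the cap is attained (the peak mover travels exactly CR) in most steps
  expect_gt(hit_cap / length(run$trajectory), 0.5)
})

test_that("termination reasons follow the documented priority", {
  p <- fvm_params(aib = 30)
  stop0 <- fvm_stop()
  far <- pop_at(rbind(c(0, 0), c(100, 0)))
  expect_equal(check_termination(far, NULL, stop0, p), "all_beyond_aib")
  # tickstop yields exactly that many records
  cfg <- standard_conditions(aib = 100, seed = 9, stop = fvm_stop(tickstop = 5))
  run <- fvm_run(cfg)
  expect_equal(run$stop_reason, "tickstop")
  expect_equal(nrow(run$records), 5L)
  # agent_stop halts the first time <= threshold agents remain
  cfg2 <- standard_conditions(aib = 100, seed = 9,
                              stop = fvm_stop(agent_stop = 30))
  run2 <- fvm_run(cfg2)
  expect_equal(run2$stop_reason, "agent_stop")
  expect_lte(n_agents(run2$final_population), 30L)
  free <- fvm_run(standard_conditions(aib = 100, seed = 9))
  below <- which(free$records$n_agents <= 30)[1]
  expect_equal(run2$iterations, below)
  expect_equal(run2$records, free$records[seq_len(below), ])
  # dt_stop fires once the computed DT exceeds the bound
  cfg3 <- standard_conditions(aib = 100, seed = 9,
                              stop = fvm_stop(dt_stop = 5))
  run3 <- fvm_run(cfg3)
  expect_equal(run3$stop_reason, "dt_stop")
  expect_gt(run3$records$dt[run3$iterations], 5)
})

test_that("a population already beyond the AIB stops with no movement", {
  cfg <- config_with_positions(rbind(c(-80, -80), c(80, 80)), aib = 30)
  run <- fvm_run(cfg)
  expect_equal(run$stop_reason, "all_beyond_aib")
  expect_equal(run$iterations, 0L)
  expect_equal(nrow(run$records), 0L)
})

test_that("runs are deterministic for a fixed seed", {
  cfg <- standard_conditions(aib = 60, seed = 17)
  r1 <- fvm_run(cfg)
  r2 <- fvm_run(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$final_population$positions,
                   r2$final_population$positions)
  expect_identical(r1$final_population$members, r2$final_population$members)
})

test_that("active and passive mass are conserved and members partition ids", {
  for (seed in c(2, 23)) {
    run <- fvm_run(standard_conditions(aib = 100, seed = seed))
    init <- run$initial_population
    final <- run$final_population
    expect_equal(sum(final$active_mass), sum(init$active_mass))
    expect_equal(sum(final$passive_mass), sum(init$passive_mass))
    expect_setequal(unlist(final$members), unlist(init$members))
    expect_false(anyDuplicated(unlist(final$members)) > 0)
  }
})

test_that("the pure-R step path reproduces the compiled engine", {
  cfg <- standard_conditions(aib = 60, seed = 31, record_trajectory = TRUE,
                             stop = fvm_stop(tickstop = 25))
  run <- fvm_run(cfg)
  set.seed(31)
  pop <- build_population(cfg$init, cfg$model)
  pop <- merge_pass(pop, cfg$model)
  et <- 0
  for (i in 1:25) {
    out <- fvm_step(pop, cfg$model, iteration = i, elapsed_time = et)
    pop <- out$population
    et <- out$record$elapsed_time
    snap <- run$trajectory[[i]]
    expect_equal(pop$positions, snap$positions, tolerance = 1e-12)
    expect_equal(pop$active_mass, snap$active_mass)
    expect_equal(out$record$dt, run$records$dt[i], tolerance = 1e-12)
    expect_equal(out$record$sum_attractive, run$records$sum_attractive[i],
                 tolerance = 1e-10)
    expect_equal(out$record$sum_repulsive, run$records$sum_repulsive[i],
                 tolerance = 1e-10)
  }
})

test_that("trajectories are invariant to the force scale g", {
  r1 <- fvm_run(standard_conditions(aib = 100, seed = 7))
  r2 <- fvm_run(standard_conditions(aib = 100, seed = 7, g = 7e-3))
  expect_equal(r1$iterations, r2$iterations)
  expect_equal(r1$final_population$positions, r2$final_population$positions,
               tolerance = 1e-9)
  g_et2_1 <- 7e-5 * r1$elapsed_time^2
  g_et2_2 <- 7e-3 * r2$elapsed_time^2
  expect_equal(g_et2_1, g_et2_2, tolerance = 1e-6)
})

test_that("whole runs are rotationally equivariant", {
  set.seed(99)
  pos0 <- matrix(rnorm(120, 0, 30), 60, 2)
  base <- fvm_run(config_with_positions(pos0, aib = 60, seed = 5))
  th <- 33
  rotated <- fvm_run(config_with_positions(rotate2(pos0, th), aib = 60,
                                           seed = 5))
  expect_equal(base$iterations, rotated$iterations)
  expect_equal(n_agents(base$final_population),
               n_agents(rotated$final_population))
  expect_equal(rotate2(base$final_population$positions, th),
               rotated$final_population$positions, tolerance = 1e-6)
})

test_that("groups only grow: member sets are nested across iterations", {
  cfg <- standard_conditions(aib = 60, seed = 41, record_trajectory = TRUE)
  run <- fvm_run(cfg)
  prev <- run$initial_population$members
  ok <- TRUE
  # nesting is transitive, so checking a subsample of iterations suffices
  idx <- unique(c(seq(1, length(run$trajectory), by = 20),
                  length(run$trajectory)))
  for (snap in run$trajectory[idx]) {
    for (m in prev) {
      # each earlier member set must live intact inside exactly one agent
      holders <- sum(vapply(snap$members, function(s) all(m %in% s), TRUE))
      if (holders != 1L) ok <- FALSE
    }
    prev <- snap$members
  }
  expect_true(ok)
  expect_gt(sum(is_group(run$final_population)), 0L)
})

test_that("results are robust to the coalescence radius", {
  finals <- lapply(c(0.1, 0.2, 0.3), function(cr) {
    fvm_run(standard_conditions(aib = 100, seed = 13,
                                coalescence_radius = cr))$final_population
  })
  counts <- vapply(finals, n_agents, 1L)
  expect_true(all(counts == counts[1]))
  for (f in finals[-2]) {
    expect_lt(max(abs(f$positions - finals[[2]]$positions)), 2)
  }
})

test_that("elapsed time grows strongly with the AIB", {
  r30 <- fvm_run(standard_conditions(aib = 30, seed = 61))
  r180 <- fvm_run(standard_conditions(aib = 180, seed = 61))
  expect_gt(r180$elapsed_time / r30$elapsed_time, 2)
  expect_true(all(diff(r30$records$elapsed_time) > 0))
})

test_that("snapshots locate the first record at a fraction of elapsed time", {
  run <- fvm_run(standard_conditions(aib = 60, seed = 3,
                                     record_trajectory = TRUE))
  half <- snapshot_at(run, 0.5)
  idx <- which(run$records$elapsed_time >= 0.5 * run$elapsed_time)[1]
  expect_equal(attr(half, "iteration"), run$records$iteration[idx])
  expect_equal(half$positions, run$trajectory[[idx]]$positions)
  expect_error(snapshot_at(run, 1.5), "fraction")
})
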