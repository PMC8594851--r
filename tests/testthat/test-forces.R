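test_that("attribute distance matches hand-worked values and is a metric", {
  p <- default_params()
  expect_equal(attribute_distance(c(3, 7), c(3, 7), p), 0)
  expect_equal(attribute_distance(c(3, 0), c(0, 4), p), 5)
  pw <- fvm_params(metric_weights = c(4, 1))
  expect_equal(attribute_distance(c(1, 0), c(0, 0), pw), 2)
  # symmetry and positivity on random pairs
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(2, 0, 50); b <- rnorm(2, 0, 50)
    expect_equal(attribute_distance(a, b, p), attribute_distance(b, a, p))
    expect_gt(attribute_distance(a, b, p), 0)
  }
  expect_error(attribute_distance(c(1, 2, 3), c(0, 0), p), "dimension")
})

test_that("pair force reproduces the worked scalar evaluations", {
  p <- default_params()
  a <- list(position = c(10, 0), active_mass = 60)
  b <- list(position = c(20, 0), active_mass = 60)
  pf <- pair_force(a, b, p)
  expect_equal(pf$force_on_b, c(-0.0084, 0))  # g*60*200/100 toward A
  expect_identical(pf$sign, "attractive")
  expect_equal(pf$dot, 200)
  expect_equal(pf$r_mag, 10)

  b2 <- list(position = c(-10, 0), active_mass = 60)
  pf2 <- pair_force(a, b2, p)
  expect_equal(pf2$force_on_b, c(-0.00105, 0))  # pushes B away from A
  expect_identical(pf2$sign, "repulsive")
})

test_that("orthogonal, blocked, and coincident pairs give zero force", {
  p <- default_params()
  a <- list(position = c(10, 0), active_mass = 60)
  ortho <- pair_force(a, list(position = c(0, 10)), p)
  expect_equal(ortho$force_on_b, c(0, 0))
  expect_identical(ortho$sign, "zero")
  expect_equal(ortho$omega, 90)

  pn <- fvm_params(aib = 30)
  far <- pair_force(a, list(position = c(50, 0)), pn)
  expect_identical(far$sign, "blocked")
  expect_equal(far$force_on_b, c(0, 0))

  coincident <- pair_force(a, list(position = c(10, 0)), p)
  expect_identical(coincident$sign, "zero")
  expect_equal(coincident$force_on_b, c(0, 0))
})

test_that("an agent at the origin neither exerts nor receives force", {
  p <- default_params()
  null_agent <- list(position = c(0, 0), active_mass = 1000)
  other <- list(position = c(30, 40), active_mass = 60)
  expect_equal(pair_force(null_agent, other, p)$force_on_b, c(0, 0))
  expect_equal(pair_force(other, null_agent, p)$force_on_b, c(0, 0))
})

test_that("quadrant sign rules hold for random agent pairs", {
  p <- default_params()
  set.seed(42)
  for (i in 1:50) {
    same <- list(position = abs(rnorm(2, 10, 5)), active_mass = 60)
    other <- list(position = abs(rnorm(2, 10, 5)), active_mass = 60)
    expect_identical(pair_force(same, other, p)$sign, "attractive")
    opp <- list(position = -abs(rnorm(2, 10, 5)), active_mass = 60)
    expect_identical(pair_force(same, opp, p)$sign, "repulsive")
  }
})

test_that("force modes post-process the scalar prefactor", {
  a <- list(position = c(10, 0), active_mass = 60)
  b_att <- list(position = c(20, 0))   # dot > 0
  b_rep <- list(position = c(-10, 0))  # dot < 0
  normal_att <- pair_force(a, b_att, default_params())$force_on_b
  normal_rep <- pair_force(a, b_rep, default_params())$force_on_b
  mode <- function(m) fvm_params(force_mode = m)
  expect_equal(pair_force(a, b_rep, mode("ATTRACT_ONLY"))$force_on_b,
               -normal_rep)
  expect_equal(pair_force(a, b_att, mode("REPEL_ONLY"))$force_on_b,
               -normal_att)
  expect_equal(pair_force(a, b_rep, mode("ZERO_REPULSIVE"))$force_on_b,
               c(0, 0))
  expect_equal(pair_force(a, b_att, mode("ZERO_REPULSIVE"))$force_on_b,
               normal_att)
  expect_equal(pair_force(a, b_att, mode("ZERO_ATTRACTIVE"))$force_on_b,
               c(0, 0))
  expect_equal(pair_force(a, b_att, mode("INVERT"))$force_on_b, -normal_att)
})

test_that("pair force magnitude agrees with the independent scalar formula", {
  p <- default_params()
  set.seed(7)
  for (i in 1:100) {
    A <- rnorm(2, 0, 40); B <- rnorm(2, 0, 40); m <- runif(1, 1, 120)
    pf <- pair_force(list(position = A, active_mass = m),
                     list(position = B), p)
    if (pf$sign %in% c("blocked", "zero")) next
    r <- sqrt(sum((A - B)^2))
    expected <- p$g * m * abs(sum(A * B)) / r^2
    expect_equal(sqrt(sum(pf$force_on_b^2)), expected, tolerance = 1e-12)
  }
})

test_that("pair force is rotationally equivariant with unit weights", {
  p <- default_params()
  set.seed(11)
  for (i in 1:25) {
    A <- rnorm(2, 0, 40); B <- rnorm(2, 0, 40); th <- runif(1, 0, 360)
    f0 <- pair_force(list(position = A, active_mass = 60),
                     list(position = B), p)$force_on_b
    fr <- pair_force(list(position = drop(rotate2(rbind(A), th)),
                          active_mass = 60),
                     list(position = drop(rotate2(rbind(B), th))),
                     p)$force_on_b
    expect_equal(fr, drop(rotate2(rbind(f0), th)), tolerance = 1e-10)
  }
})

test_that("net force sums pair forces and respects square-corner symmetry", {
  p <- default_params()
  # square corners: adjacent contributions vanish, opposite corner repels
  sq <- pop_at(geometry_preset("square", circumradius = sqrt(2) * 30))
  for (i in 1:4) {
    f <- net_force(i, sq, p)
    outward <- sq$positions[i, ] / sqrt(sum(sq$positions[i, ]^2))
    # force is parallel to the diagonal, pointing outward
    expect_equal(f / sqrt(sum(f^2)), outward, tolerance = 1e-12)
  }
  # collinear same-ray agents: superposition equals the per-pair sum
  tri <- pop_at(rbind(c(10, 0), c(20, 0), c(40, 0)))
  f2 <- net_force(2, tri, p)
  manual <- pair_force(list(position = c(10, 0), active_mass = 60),
                       list(position = c(20, 0)), p)$force_on_b +
            pair_force(list(position = c(40, 0), active_mass = 60),
                       list(position = c(20, 0)), p)$force_on_b
  expect_equal(f2, manual)
  # a lone agent feels nothing
  expect_equal(net_force(1, pop_at(rbind(c(5, 5))), p), c(0, 0))
})

test_that("displacement is linear in force and quadratic in dt", {
  expect_equal(displacement(c(0, 0), 60, 1), c(0, 0))
  expect_equal(displacement(c(-0.0084, 0), 60, 1), c(-1.4e-4, 0))
  f <- c(0.3, -0.2)
  expect_equal(displacement(f, 10, 2), 4 * displacement(f, 10, 1))
  expect_equal(displacement(2 * f, 10, 1), 2 * displacement(f, 10, 1))
  expect_error(displacement(f, 0, 1), "positive")
  expect_error(displacement(f, 10, 0), "positive")
})

test_that("componentwise formulas extend to higher dimensions", {
  p5 <- fvm_params(dimension = 5)
  A <- c(10, 0, 0, 0, 0); B <- c(20, 0, 0, 0, 0)
  pf <- pair_force(list(position = A, active_mass = 60),
                   list(position = B), p5)
  expect_equal(pf$force_on_b, c(-0.0084, 0, 0, 0, 0))
})
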