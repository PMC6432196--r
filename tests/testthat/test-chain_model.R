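test_that("minimal bond angle follows the steric-overlap geometry", {
  # rigid-rod limit: only angle pi remains
  expect_equal(min_bond_angle(0.5), pi, tolerance = 1e-12)
  # tangent spheres: equilateral triangle of the three centres
  expect_equal(min_bond_angle(1.0), pi / 3, tolerance = 1e-12)
  expect_equal(min_bond_angle(0.55), 2 * asin(1 / 1.1), tolerance = 1e-12)
  expect_error(min_bond_angle(0.49), "no valid conformation")
  # monotonically decreasing in L
  ls <- seq(0.5, 1, by = 0.01)
  expect_true(all(diff(min_bond_angle(ls)) < 0))
})

test_that("a 3-monomer chain at the minimal angle has next-nearest distance 1", {
  for (L in c(0.51, 0.55, 0.7, 0.85, 1.0)) {
    conf <- planar_chain(L, min_bond_angle(L))
    r13 <- sqrt(sum((conf[3, ] - conf[1, ])^2))
    expect_equal(r13, 1, tolerance = 1e-9)
  }
})

test_that("stiffness regimes split at 2L = lambda and at L = 1", {
  expect_identical(classify_regime(0.55, 1.1), "stiff")
  expect_identical(classify_regime(0.56, 1.1), "semi-flexible")
  expect_identical(classify_regime(1.0, 1.1), "flexible")
  expect_identical(classify_regime(0.55 + 1e-9, 1.1), "semi-flexible")
  expect_identical(classify_regime(model_params(10, 0.52)), "stiff")
  # boundary scales with the well width
  expect_identical(classify_regime(0.6, 1.2), "stiff")
})

test_that("square-well pair potential has the three branches", {
  expect_identical(pair_potential(0.99, 1.1), Inf)
  expect_identical(pair_potential(1.05, 1.1), -1)
  expect_identical(pair_potential(1.11, 1.1), 0)
  # inclusive well boundaries
  expect_identical(pair_potential(1, 1.1), -1)
  expect_identical(pair_potential(1.1, 1.1), -1)
  expect_identical(pair_potential(1.3, 1.3, well_depth = 2), -2)
  expect_error(pair_potential(-0.1, 1.1), ">= 0")
})

test_that("straight-rod energies count next-nearest well contacts", {
  p20 <- model_params(20, 0.53)
  expect_identical(total_energy(straight_rod(p20), p20), -18)
  p3 <- model_params(3, 1.0)
  expect_identical(total_energy(straight_rod(p3), p3), 0)
  p40 <- model_params(40, 0.53)
  # brute-force count over explicit rod coordinates: |i-j| = 2 pairs sit at
  # 1.06, every farther pair at >= 1.59
  rod <- straight_rod(p40)
  d <- as.matrix(dist(rod))
  cnt <- sum(d[upper.tri(d)][abs(row(d)[upper.tri(d)] - col(d)[upper.tri(d)]) >= 2] <= 1.1 &
             d[upper.tri(d)][abs(row(d)[upper.tri(d)] - col(d)[upper.tri(d)]) >= 2] >= 1)
  expect_identical(cnt, 38L)
  expect_identical(total_energy(rod, p40), -38)
})

test_that("hard-core violations give a forbidden (infinite) energy", {
  p <- model_params(4, 0.8)
  conf <- planar_chain(0.8, c(pi, pi))
  conf[4, ] <- conf[2, ] + c(0.99, 0, 0)  # r24 = 0.99 < 1
  conf[4, ] <- conf[2, ] + 0.8 * (conf[4, ] - conf[2, ]) /
    sqrt(sum((conf[4, ] - conf[2, ])^2))  # keep bond length valid
  # force a non-bonded pair inside the core instead: bend sharply
  sharp <- planar_chain(0.8, c(0.3, 0.3))
  expect_false(is_self_avoiding(sharp))
  expect_identical(total_energy(sharp, p), Inf)
  expect_true(is_self_avoiding(straight_rod(p)))
  # bonded pairs are exempt: a dimer is always valid
  p2 <- model_params(2, 0.6)
  expect_true(is_self_avoiding(straight_rod(p2)))
})

test_that("energy is integer-valued and rigid-motion invariant on random chains", {
  set.seed(41)
  p <- model_params(6, 0.8)
  for (k in 1:20) {
    conf <- random_valid_chain(p)
    e <- total_energy(conf, p)
    expect_true(is.finite(e))
    expect_identical(e, round(e))
    expect_gte(e, -choose(5, 2))
    expect_lte(e, 0)
    rot <- random_rotation_matrix()
    moved <- conf %*% rot + matrix(stats::rnorm(3), p$n, 3, byrow = TRUE)
    expect_identical(total_energy(moved, p), e)
  }
})

test_that("stiff chains have permanent next-nearest contacts: E <= -(N-2)", {
  set.seed(42)
  p <- model_params(8, 0.54)   # 2L = 1.08 <= lambda
  for (k in 1:10) {
    conf <- random_valid_chain(p)
    expect_lte(total_energy(conf, p), -(p$n - 2))
  }
})

test_that("parameter validation enforces the model ranges", {
  expect_error(model_params(1, 0.8), ">= 2")
  expect_error(model_params(10, 0.5), "rigid-rod")
  expect_error(model_params(10, 1.2), "\\(0.5, 1\\]")
  expect_error(model_params(10, 0.8, well_width = 1), "> 1")
  expect_error(validate_conformation(straight_rod(model_params(5, 0.8)),
                                     model_params(6, 0.8)), "expect 6")
  bad <- straight_rod(model_params(5, 0.8))
  bad[3, 1] <- bad[3, 1] + 1e-5
  expect_error(validate_conformation(bad, model_params(5, 0.8)),
               "bond length")
})
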