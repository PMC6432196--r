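test_that("gain schedule has the plateau-then-1/t form", {
  sc <- samc_schedule(gamma0 = 0.01, t0 = 1e5)
  expect_identical(gamma_schedule(1, sc), 0.01)
  expect_identical(gamma_schedule(1e5, sc), 0.01)
  expect_equal(gamma_schedule(1e6, sc), 0.001, tolerance = 1e-12)
  expect_equal(gamma_schedule(10 * 1e5, sc), 0.01 / 10, tolerance = 1e-12)
  expect_true(all(diff(gamma_schedule(1:2000, samc_schedule(1, 500))) <= 0))
  expect_error(samc_schedule(0, 10), "> 0")
  expect_error(gamma_schedule(0, sc), ">= 1")
})

test_that("gain partial sums diverge while nu-power sums converge", {
  sc <- samc_schedule(gamma0 = 0.01, t0 = 1e3)
  g <- gamma_schedule(1:1e6, sc)
  s1 <- cumsum(g)
  s15 <- cumsum(g^1.5)
  # per-decade increments: sum(gamma) grows by ~gamma0 t0 ln10 every decade
  # (logarithmic divergence), sum(gamma^1.5) increments shrink ~sqrt(10)-fold
  d1 <- c(s1[1e5] - s1[1e4], s1[1e6] - s1[1e5])
  expect_equal(d1[2] / d1[1], 1, tolerance = 0.01)
  expect_equal(d1[2], 0.01 * 1e3 * log(10), tolerance = 0.01)
  d15 <- c(s15[1e5] - s15[1e4], s15[1e6] - s15[1e5])
  expect_equal(d15[1] / d15[2], sqrt(10), tolerance = 0.05)
  # analytic tail bound: the remaining mass beyond 1e6 is a vanishing
  # fraction, so the nu = 1.5 series is summable
  tail_bound <- 2 * (0.01 * 1e3)^1.5 / sqrt(1e6)
  expect_lt(tail_bound, 0.05 * s15[1e6])
})

test_that("acceptance probability is the flat-histogram rule in log space", {
  expect_identical(acceptance_probability(0.3, 0.3), 1)
  expect_identical(acceptance_probability(1, 1 - log(2)), 1)
  expect_equal(acceptance_probability(1, 1 + log(2)), 0.5, tolerance = 1e-12)
  expect_error(acceptance_probability(Inf, 0), "finite")
})

test_that("samc_update shifts the accepted bin against all others", {
  dos <- dos_estimate(c(-1, 0))
  up <- samc_update(dos, -1, gamma = 0.1)
  expect_equal(up$ln_g, c(0.05, -0.05), tolerance = 1e-15)
  expect_identical(up$visits, c(1, 0))
  # sum conservation under arbitrary update sequences
  set.seed(12)
  dos <- dos_estimate(-5:0, ln_g = rnorm(6))
  s0 <- sum(dos$ln_g)
  for (k in 1:2000)
    dos <- samc_update(dos, sample(-5:0, 1), gamma = runif(1))
  expect_equal(sum(dos$ln_g), s0, tolerance = 1e-9)
  # single-bin grid: update is a no-op on ln_g
  one <- samc_update(dos_estimate(0), 0, 0.5)
  expect_identical(one$ln_g, 0)
  expect_error(samc_update(dos_estimate(0), -3, 0.1), "off the grid")
})

test_that("runs are deterministic given the seed", {
  p <- model_params(5, 0.8)
  a <- run_samc(p, samc_schedule(1, 1e3), n_steps = 5e4, seed = 31)
  b <- run_samc(p, samc_schedule(1, 1e3), n_steps = 5e4, seed = 31)
  expect_identical(a$dos$ln_g, b$dos$ln_g)
  expect_identical(a$dos$visits, b$dos$visits)
  expect_identical(a$final_conf, b$final_conf)
  c2 <- run_samc(p, samc_schedule(1, 1e3), n_steps = 5e4, seed = 32)
  expect_false(identical(a$dos$visits, c2$dos$visits))
})

test_that("a split run resumed from its checkpoint matches the unsplit run", {
  p <- model_params(4, 0.8)
  sc <- samc_schedule(1, 1e3)
  whole <- run_samc(p, sc, n_steps = 4e4, seed = 77)
  part1 <- run_samc(p, sc, n_steps = 2e4, seed = 77)
  part2 <- run_samc(p, sc, n_steps = 2e4, seed = NULL, init = part1)
  expect_identical(part2$dos$ln_g_final, whole$dos$ln_g_final)
  expect_identical(part2$dos$visits, whole$dos$visits)
  expect_identical(part2$final_conf, whole$final_conf)
})

test_that("stiff N=20 chains only visit energies at or below -18", {
  run <- run_samc(model_params(20, 0.53), samc_schedule(1, 1e4),
                  n_steps = 1e6, seed = 5)
  expect_true(all(run$dos$energy[run$dos$visits > 0] <= -18))
  expect_identical(max(run$dos$energy), -18)
})

test_that("SAMC reproduces the exact trimer contact statistics", {
  p <- model_params(3, 1.0)
  d <- samc_lng_differences(p, samc_schedule(1, 1e3), n_steps = 2e6,
                            seed = 400, k = 4, e_ref = 0)
  target <- log(n3_contact_fraction(1, 1.1) / (1 - n3_contact_fraction(1, 1.1)))
  row <- d[d$energy == -1, ]
  expect_lt(abs(row$dlng_mean - target), 3 * row$dlng_se + 0.02)
})

test_that("visit histogram flattens as the gain decays", {
  # flatness of the visited-bin histogram, measured per window as
  # (max - min)/mean, trends down between the early and late thirds
  p <- model_params(4, 0.8)
  sc <- samc_schedule(1, 1e3)
  seg1 <- run_samc(p, sc, n_steps = 3e4, seed = 91)
  seg2 <- run_samc(p, sc, n_steps = 3e5, seed = NULL, init = seg1)
  flat <- function(run, prev) {
    v <- run$dos$visits - ifelse(is.na(match(run$dos$energy, prev$dos$energy)),
                                 0, prev$dos$visits[match(run$dos$energy, prev$dos$energy)])
    v <- v[v > 0]
    (max(v) - min(v)) / mean(v)
  }
  v1 <- seg1$dos$visits[seg1$dos$visits > 0]
  f1 <- (max(v1) - min(v1)) / mean(v1)
  f2 <- flat(seg2, seg1)
  expect_lt(f2, f1)
})

test_that("the visited energy set only grows and ground state matches", {
  p <- model_params(5, 0.7)
  sc <- samc_schedule(1, 1e3)
  s1 <- run_samc(p, sc, n_steps = 2e4, seed = 13)
  s2 <- run_samc(p, sc, n_steps = 2e4, seed = NULL, init = s1)
  lev1 <- s1$dos$energy[s1$dos$visits > 0]
  lev2 <- s2$dos$energy[s2$dos$visits > 0]
  expect_true(all(lev1 %in% lev2))
  expect_identical(s2$ground_state$energy, min(lev2))
  e_g <- total_energy(s2$ground_state$conf, p)
  expect_identical(e_g, s2$ground_state$energy)
})

test_that("fixed grid policy errors on energies outside the declared range", {
  p <- model_params(5, 0.7)
  expect_error(
    run_samc(p, samc_schedule(1, 1e3), n_steps = 5e4, seed = 3,
             grid_policy = "fixed", grid_range = c(-1, 0)),
    "outside the declared fixed grid")
  ok <- run_samc(p, samc_schedule(1, 1e3), n_steps = 2e4, seed = 3,
                 grid_policy = "fixed", grid_range = c(-6, 0))
  expect_identical(ok$dos$energy, as.numeric(-6:0))
})
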