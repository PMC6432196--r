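test_that("micro-canonical derivatives are exact on linear and quadratic S", {
  e <- -20:0
  lin <- dos_estimate(e, ln_g = 0.7 * e, visits = rep(1, 21))
  mc <- micro_curves(lin)
  expect_equal(mc$beta_micro[2:20], rep(0.7, 19), tolerance = 1e-12)
  expect_equal(mc$gamma_E[2:20], rep(0, 19), tolerance = 1e-12)
  quad <- dos_estimate(e, ln_g = -0.03 * e^2, visits = rep(1, 21))
  mq <- micro_curves(quad)
  expect_equal(mq$gamma_E[2:20], rep(-0.06, 19), tolerance = 1e-12)
  expect_true(all(is.na(mc$beta_micro[c(1, 21)])))
})

test_that("an entropy maximum flips the micro-canonical temperature sign", {
  e <- -20:0
  dos <- dos_estimate(e, ln_g = -0.05 * (e + 8)^2, visits = rep(1, 21))
  mc <- micro_curves(dos)
  below <- mc$beta_micro[mc$energy < -8 & !is.na(mc$beta_micro)]
  above <- mc$beta_micro[mc$energy > -8 & !is.na(mc$beta_micro)]
  expect_true(all(below > 0))
  expect_true(all(above < 0))
})

test_that("interior gaps are refused unless explicitly allowed", {
  dos <- dos_estimate(c(-6, -5, -3, -2, -1, 0), ln_g = rep(0, 6),
                      visits = rep(1, 6))
  expect_error(micro_curves(dos), "unpopulated interior")
  mc <- micro_curves(dos, allow_gaps = TRUE)
  # stencils never straddle the gap
  expect_true(is.na(mc$gamma_E[mc$energy == -3]))
  expect_false(is.na(mc$gamma_E[mc$energy == -1]))
})

test_that("transition order follows the sign of the gamma peak", {
  # synthetic gamma shapes injected via an entropy whose second difference
  # is the wanted curve
  e <- -30:0
  gamma_target <- 0.3 * exp(-(e + 15)^2 / 8) - 0.05
  s <- cumsum(c(0, cumsum(gamma_target)))[1:31]
  rec <- classify_transitions_micro(
    micro_curves(dos_estimate(e, s, visits = rep(1, 31))))
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$order, "first")
  expect_equal(rec$location, -15, tolerance = 1)
  rec2 <- classify_transitions_micro(
    micro_curves(concave_bump_dos()))
  expect_identical(rec2$order, "second")
  expect_true(all(rec2$value < 0))
  expect_equal(rec2$location, -30, tolerance = 1)
  # strictly monotone gamma: no transitions
  s3 <- cumsum(c(0, cumsum(seq(-0.1, 0.1, length.out = 29))))
  rec3 <- classify_transitions_micro(
    micro_curves(dos_estimate(-29:0, c(s3, 0)[1:30], visits = rep(1, 30))))
  expect_identical(nrow(rec3), 0L)
})

test_that("two-Gaussian DOS gives a first-order record and bimodal P(E|T)", {
  dos <- two_gaussian_dos(a = -40, b = -10, s = 4, t_match = 1)
  rec <- classify_transitions_micro(micro_curves(dos))
  first <- rec[rec$order == "first", ]
  expect_gte(nrow(first), 1L)
  expect_true(any(abs(first$location - (-25)) < 6))
  pd <- energy_distribution(dos, 1)
  bm <- detect_bimodality(pd)
  expect_true(bm$is_bimodal)
  expect_equal(sort(bm$peaks), c(-40, -10), tolerance = 3)
})

test_that("log partition function matches closed forms", {
  single <- dos_estimate(0, ln_g = 0, visits = 1)
  expect_equal(log_partition_function(single, c(0.1, 1, 10)), c(0, 0, 0),
               tolerance = 1e-12)
  two <- dos_estimate(c(-1, 0), ln_g = c(0, 0), visits = c(1, 1))
  expect_equal(log_partition_function(two, 1), log(1 + exp(1)),
               tolerance = 1e-12)
  # high-T limit: ln sum g(E)
  some <- dos_estimate(-3:0, ln_g = c(1, 2, 0.5, 0), visits = rep(1, 4))
  expect_equal(log_partition_function(some, 1e8),
               log(sum(exp(c(1, 2, 0.5, 0)))), tolerance = 1e-6)
  expect_error(log_partition_function(two, 0), "> 0")
  # extreme beta stays finite via the log-sum-exp shift
  expect_true(is.finite(log_partition_function(two, 1e-3)))
})

test_that("specific heat matches the Schottky closed form and stays positive", {
  two <- dos_estimate(c(-1, 0), ln_g = c(0, 0), visits = c(1, 1))
  # two-level system at T = 1: C = e / (1 + e)^2
  expect_equal(specific_heat(two, 1), exp(1) / (1 + exp(1))^2,
               tolerance = 1e-12)
  expect_equal(specific_heat(dos_estimate(0, 0, 1), c(0.3, 1)), c(0, 0),
               tolerance = 1e-12)
  set.seed(5)
  dos <- dos_estimate(-49:0, ln_g = cumsum(runif(50, 0, 2)),
                      visits = rep(1, 50))
  temps <- seq(0.05, 2, by = 0.05)
  expect_true(all(specific_heat(dos, temps) >= 0))
})

test_that("fluctuation and temperature-derivative specific heats agree", {
  set.seed(6)
  dos <- dos_estimate(-49:0, ln_g = cumsum(runif(50, 0, 2)),
                      visits = rep(1, 50))
  temps <- seq(0.2, 2, by = 0.1)
  cf <- specific_heat(dos, temps, method = "fluctuation")
  cd <- specific_heat(dos, temps, method = "derivative")
  expect_equal(cd, cf, tolerance = 1e-6)
})

test_that("mean energy equals T^2 dlnZ/dT", {
  set.seed(7)
  dos <- dos_estimate(-49:0, ln_g = cumsum(runif(50, 0, 2)),
                      visits = rep(1, 50))
  for (tt in c(0.3, 0.7, 1.5)) {
    h <- 1e-5
    d1 <- (log_partition_function(dos, tt + h) -
             log_partition_function(dos, tt - h)) / (2 * h)
    expect_equal(mean_energy(dos, tt), tt^2 * d1, tolerance = 1e-6)
  }
})

test_that("canonical averages reweight energy-resolved observables", {
  two <- dos_estimate(c(-1, 0), ln_g = c(0, 0), visits = c(1, 1))
  obs <- data.frame(energy = c(-1, 0), count = c(5, 5), rg2_mean = c(1, 0))
  class(obs) <- c("energy_observables", "data.frame")
  # closed form: <O>(T=1) = e/(1+e)
  expect_equal(canonical_average(obs, two, 1), exp(1) / (1 + exp(1)),
               tolerance = 1e-12)
  # constant observable is temperature independent
  obsc <- transform(obs, rg2_mean = 4.2)
  class(obsc) <- c("energy_observables", "data.frame")
  expect_equal(canonical_average(obsc, two, c(0.2, 1, 5)), rep(4.2, 3),
               tolerance = 1e-12)
  # T -> 0 limit: value at the lowest populated level
  expect_equal(canonical_average(obs, two, 0.01), 1, tolerance = 1e-6)
  # missing coverage on a weighty level warns and renormalizes
  obs_m <- data.frame(energy = c(-1, 0), count = c(5, 0), rg2_mean = c(1, 0))
  class(obs_m) <- c("energy_observables", "data.frame")
  expect_warning(v <- canonical_average(obs_m, two, 1), "renormalizing")
  expect_equal(v, 1, tolerance = 1e-12)
})

test_that("energy distributions normalize and classify modality", {
  set.seed(8)
  dos <- dos_estimate(-49:0, ln_g = cumsum(runif(50, 0, 2)),
                      visits = rep(1, 50))
  for (tt in c(0.1, 0.5, 2)) {
    pd <- energy_distribution(dos, tt)
    expect_equal(sum(pd$prob), 1, tolerance = 1e-12)
  }
  # single-Gaussian DOS at its matched temperature is unimodal
  e <- -60:0
  lg <- -(e + 30)^2 / (2 * 16) + e
  uni <- dos_estimate(e, lg, visits = rep(1, 61))
  expect_false(detect_bimodality(energy_distribution(uni, 1))$is_bimodal)
})

test_that("canonical transition location pools observable peaks", {
  tgrid <- seq(0.1, 1.5, by = 0.01)
  mk <- function(center) data.frame(T = tgrid,
                                    value = exp(-(tgrid - center)^2 / 0.005))
  same <- locate_transitions_canonical(list(a = mk(0.5), b = mk(0.5)))
  expect_equal(same$location, 0.5, tolerance = 1e-9)
  expect_equal(same$upper - same$lower, 0, tolerance = 1e-9)
  two <- locate_transitions_canonical(list(cv = mk(0.50), drg = mk(0.54)))
  expect_equal(two$location, 0.52, tolerance = 1e-9)
  expect_equal(c(two$lower, two$upper), c(0.50, 0.54), tolerance = 1e-9)
  flat <- locate_transitions_canonical(
    list(a = data.frame(T = tgrid, value = rep(1, length(tgrid)))))
  expect_identical(nrow(flat), 0L)
})

test_that("canonical <E>(T) inverts the micro-canonical temperature", {
  # strictly concave synthetic S(E): at beta = dS/dE the canonical mean
  # energy must sit within one grid spacing of E (checked away from the
  # grid boundaries, where the Boltzmann weight is untruncated)
  e <- -50:0
  dos <- dos_estimate(e, ln_g = -0.05 * (e + 50)^2 + 4 * (e + 50),
                      visits = rep(1, 51))
  mc <- micro_curves(dos)
  for (i in seq(15, 40, by = 5)) {
    beta <- mc$beta_micro[i]
    em <- mean_energy(dos, 1 / beta)
    expect_lt(abs(em - mc$energy[i]), 1)
  }
})

test_that("Savitzky-Golay smoothing is recorded, never silent", {
  set.seed(9)
  dos <- dos_estimate(-30:0, ln_g = cumsum(runif(31, 0, 2)) + rnorm(31, 0, 0.05),
                      visits = rep(1, 31))
  raw <- micro_curves(dos)
  sm <- micro_curves(dos, smoothing = list(window = 7, order = 2))
  expect_null(attr(raw, "smoothing"))
  expect_identical(attr(sm, "smoothing"), list(window = 7, order = 2))
  expect_false(identical(raw$S, sm$S))
})
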