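test_that("the logistic midpoint is recovered on a noise-free sigmoid", {
  tr <- logistic_trace(t50 = 36000)
  ht <- extract_half_time(tr)
  expect_equal(ht$half_time, 36000, tolerance = 900 / 36000)
  # baseline/plateau come from the flat phases: exact to ~0.2% amplitude
  expect_equal(ht$fitted_baseline, 100, tolerance = 0.02)
  expect_equal(ht$fitted_plateau, 1100, tolerance = 0.005)
  expect_identical(ht$fit$flag, "ok")
})

test_that("sigmoid half-time agrees with the level-crossing oracle", {
  p <- default_kinetics("secondary")
  sim <- simulate_aggregation(p, seq(0, 2e5, by = 900))
  ht <- extract_half_time(sim)
  lvl <- (ht$fitted_baseline + ht$fitted_plateau) / 2
  t_cross <- crossing_time(sim$time, sim$signal, lvl)
  expect_lt(abs(ht$half_time - t_cross) / t_cross, 0.02)
})

test_that("flat traces are classified as no aggregation, not a number", {
  set.seed(1)
  tg <- seq(0, 1e5, by = 900)
  tr <- kinetic_trace(tg, rnorm(length(tg), 100, 3))
  ht <- extract_half_time(tr)
  expect_true(is.na(ht$half_time))
  expect_identical(ht$fit$flag, "no_aggregation")
})

test_that("an unfinished transition is flagged and warned about", {
  tr <- logistic_trace(t50 = 9e4, s = 8000, tmax = 9.3e4)
  expect_warning(ht <- extract_half_time(tr), "incomplete")
  expect_identical(ht$fit$flag, "incomplete")
  expect_true(is.finite(ht$half_time))
})

test_that("plate normalization recovers the exact mass-fraction scale", {
  cfg <- generator_config(rng_seed = 1, noise_sd = 0, n_reps = 1)
  p <- default_kinetics("secondary")
  trs <- gen_dilution_series(cfg, p, duration = 80 * 3600)
  nrm <- normalize_plate(trs)
  for (tr in nrm) {
    pp <- tr$meta$params
    sim <- simulate_aggregation(pp, tr$time)
    pred <- (sim$signal * pp$m_tot - pp$M_0) / (pp$m_tot - pp$M_0)
    expect_lt(sqrt(mean((tr$signal - pred)^2)), 0.01)
  }
})

test_that("scaling exponent handles exact power laws and edge cases", {
  m0 <- c(3, 5, 8, 12) * 1e-6
  expect_equal(scaling_exponent(rep(3600, 4), m0)$gamma, 0, tolerance = 1e-10)
  expect_equal(scaling_exponent(1e-2 / m0, m0)$gamma, -1, tolerance = 1e-10)
  expect_error(scaling_exponent(c(1, 2), c(1e-6, 2e-6)), "3 distinct")
  expect_error(scaling_exponent(c(1, -2, 3), m0[1:3]), "positive")
})

test_that("fragmentation-dominated dilution series scales as -1/2", {
  cfg <- generator_config(rng_seed = 1, noise_sd = 0, n_reps = 1)
  trs <- gen_dilution_series(cfg, default_kinetics("fragmentation"))
  t12 <- vapply(trs, half_time, numeric(1))
  m0 <- vapply(trs, function(x) x$meta$monomer_uM, numeric(1)) * 1e-6
  gam <- scaling_exponent(t12, m0)$gamma
  expect_equal(gam, -0.5, tolerance = 0.05)
})
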