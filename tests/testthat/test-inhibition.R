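test_that("normalized half-time is exactly 1 against itself and scales", {
  ctrl <- logistic_trace(t50 = 36000)
  expect_equal(normalized_half_time(ctrl, ctrl), 1, tolerance = 1e-8)
  slow <- logistic_trace(t50 = 72000, tmax = 2e5)
  expect_equal(normalized_half_time(slow, ctrl), 2, tolerance = 0.01)
})

test_that("a flat control invalidates the assay", {
  set.seed(2)
  tg <- seq(0, 1e5, by = 900)
  flat <- kinetic_trace(tg, rnorm(length(tg), 100, 3))
  expect_error(normalized_half_time(logistic_trace(), flat), "invalid assay")
  # a fully arrested compound well reads as an unbounded extension
  expect_identical(normalized_half_time(flat, logistic_trace()), Inf)
})

test_that("hit classes partition every finite ratio with strict thresholds", {
  expect_identical(classify_hit(1.6), "potent")
  expect_identical(classify_hit(2.5), "highly_potent")
  expect_identical(classify_hit(1.0), "inactive")
  expect_identical(classify_hit(0.5), "inducer")
  # strictness at the boundaries
  expect_identical(classify_hit(1.5), "inactive")
  expect_identical(classify_hit(2.0), "potent")
  # totality over a grid
  grid <- seq(0.1, 3.5, by = 0.05)
  cls <- classify_hit(grid)
  expect_true(all(cls %in% c("inactive", "potent", "highly_potent",
                             "inducer")))
  expect_error(classify_hit(NA_real_), "NA")
})

test_that("elongation slope is the OLS slope over the stated window", {
  tg <- seq(0, 12 * 3600, by = 900)
  lin <- kinetic_trace(tg, 50 + 0.02 * tg)
  expect_equal(elongation_slope(lin), 0.02, tolerance = 1e-10)
  # the window is the first 10 h regardless of trace duration
  tg2 <- seq(0, 48 * 3600, by = 900)
  bent <- kinetic_trace(tg2, 50 + 0.02 * pmin(tg2, 10 * 3600))
  expect_equal(elongation_slope(bent), 0.02, tolerance = 1e-10)
  expect_error(elongation_slope(kinetic_trace(tg[tg < 3600 * 5],
                                              tg[tg < 3600 * 5])),
               "window exceeds")
  # noisy recovery within 2 SE
  set.seed(3)
  noisy <- kinetic_trace(tg, 50 + 0.02 * tg + rnorm(length(tg), 0, 5))
  est <- elongation_slope(noisy, se = TRUE)
  expect_lt(abs(est[["slope"]] - 0.02), 2 * est[["se"]])
})

test_that("kic50 is the 50-crossing of the normalized rate curve", {
  doses <- c(0.6, 1.2, 2.5, 5, 10, 20) * 1e-6
  t12c <- 19 * 3600
  # exact logistic with midpoint 5 uM, Hill 1
  t12 <- t12c * (1 + doses / 5e-6)
  k <- kic50(doses, t12, t12c)
  expect_equal(k$kic50, 5e-6, tolerance = 1e-4)
  expect_identical(k$flag, "ok")
  # no inhibition: only the bound is reported
  k0 <- kic50(doses, rep(t12c, 6), t12c)
  expect_identical(k0$flag, "weak_inhibition")
  expect_true(is.na(k0$kic50))
  expect_match(k0$bound, "> 2e-05")
  expect_error(kic50(doses[1:3], t12[1:3], t12c), ">= 4 doses")
})

test_that("kic50 is equivariant under dose rescaling", {
  doses <- c(0.6, 1.2, 2.5, 5, 10, 20) * 1e-6
  t12c <- 19 * 3600
  set.seed(4)
  t12 <- t12c * (1 + (doses / 3e-6)^1.4) * exp(rnorm(6, 0, 0.02))
  k1 <- kic50(doses, t12, t12c)
  k2 <- kic50(doses * 10, t12, t12c)
  expect_equal(k2$kic50 / k1$kic50, 10, tolerance = 1e-6)
})

test_that("noise-free inhibitor dosing never shortens the half-time", {
  cfg <- generator_config(rng_seed = 1, noise_sd = 0, n_reps = 1)
  ds <- gen_inhibitor_doses(cfg, "cpd", k2_reduction = 0.9,
                            kplus_reduction = 0.2,
                            duration_low = 72 * 3600)
  ctrl <- ds$traces[[1]][[1]]
  ratios <- vapply(seq_along(ds$doses), function(i) {
    suppressWarnings(normalized_half_time(ds$traces[[i]][[1]], ctrl))
  }, numeric(1))
  expect_true(all(diff(ratios[order(ds$doses)]) >= -0.02))
})

test_that("zero planted effect fits to zero reduction in both constants", {
  cfg <- generator_config(rng_seed = 9, noise_sd = 0, n_reps = 1)
  ds <- gen_inhibitor_doses(cfg, "null_cpd", k2_reduction = 0,
                            kplus_reduction = 0,
                            doses = c(0, 20e-6),
                            duration_low = 48 * 3600)
  nds <- normalize_dose_series(ds)
  base <- update_params(default_kinetics("secondary"),
                        k_2 = 600, k_plus = 3e4)
  mr <- fit_dose_mechanism(nds, base, n_starts = 2, seed = 5)
  expect_lt(abs(mr$delta_k2), 0.02)
  expect_lt(abs(mr$delta_kplus), 0.02)
})

test_that("a pure elongation inhibitor does not leak into k_2", {
  cfg <- generator_config(rng_seed = 11)
  ds <- gen_inhibitor_doses(cfg, "kplus_only", k2_reduction = 0,
                            kplus_reduction = 0.5,
                            doses = c(0, 20e-6),
                            duration_low = 48 * 3600)
  nds <- normalize_dose_series(ds)
  base <- update_params(default_kinetics("secondary"),
                        k_2 = 600, k_plus = 3e4)
  mr <- fit_dose_mechanism(nds, base, n_starts = 2, seed = 5)
  expect_lt(abs(mr$delta_k2), 0.05)
  expect_lt(abs(mr$delta_kplus - 0.5), 0.05)
})

test_that("dose series validation catches malformed designs", {
  tg <- seq(0, 3600, by = 900)
  tr <- list(list(kinetic_trace(tg, tg)), list(kinetic_trace(tg, tg)))
  expect_error(dose_series("x", c(1e-6, 1e-6), tr), "unique")
  expect_error(dose_series("x", c(1e-6, 2e-6), tr), "control")
  expect_error(dose_series("x", c(0, 1e-6), tr[1]), "per dose")
})
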