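test_that("every generator is bit-identical under a fixed seed", {
  cfg <- generator_config(rng_seed = 5)
  a <- gen_dilution_series(cfg, default_kinetics("secondary"),
                           monomer_concs = c(4e-6, 8e-6),
                           duration = 24 * 3600)
  b <- gen_dilution_series(cfg, default_kinetics("secondary"),
                           monomer_concs = c(4e-6, 8e-6),
                           duration = 24 * 3600)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
  t1 <- gen_fp_titration(cfg, 1e-6)
  t2 <- gen_fp_titration(cfg, 1e-6)
  expect_identical(t1$delta_mP, t2$delta_mP)
  r1 <- gen_rate_response(cfg, 2.6e-6)
  r2 <- gen_rate_response(cfg, 2.6e-6)
  expect_identical(r1$half_times, r2$half_times)
})

test_that("zero noise reproduces the model curves exactly", {
  cfg <- generator_config(rng_seed = 1, noise_sd = 0, n_reps = 1)
  trs <- gen_dilution_series(cfg, default_kinetics("secondary"),
                             monomer_concs = 5e-6, duration = 24 * 3600)
  tr <- trs[[1]]
  pp <- tr$meta$params
  sim <- simulate_aggregation(pp, tr$time)
  clean <- cfg$offset + cfg$gain * (sim$signal * pp$m_tot - pp$M_0)
  expect_equal(tr$signal, clean, tolerance = 1e-10)
})

test_that("empirical noise matches the configured SD", {
  cfg <- generator_config(rng_seed = 3, noise_sd = 12, n_reps = 3)
  trs <- gen_dilution_series(cfg, default_kinetics("secondary"),
                             monomer_concs = 5e-6, duration = 40 * 3600)
  cfg0 <- generator_config(rng_seed = 3, noise_sd = 0, n_reps = 1)
  clean <- gen_dilution_series(cfg0, default_kinetics("secondary"),
                               monomer_concs = 5e-6,
                               duration = 40 * 3600)[[1]]$signal
  resid <- unlist(lapply(trs, function(tr) tr$signal - clean))
  expect_gt(length(resid), 100)
  expect_lt(abs(sd(resid) / 12 - 1), 0.1)
})

test_that("planted dose multipliers hit the construction exactly", {
  cfg <- generator_config(rng_seed = 2, noise_sd = 0, n_reps = 1)
  ds <- gen_inhibitor_doses(cfg, "x", k2_reduction = 0.97,
                            kplus_reduction = 0.29,
                            duration_low = 12 * 3600,
                            duration_high = 6 * 3600)
  truth <- attr(ds, "truth")
  i_top <- which.max(truth$dose); i_ctl <- which.min(truth$dose)
  expect_equal(truth$k2_mult[i_ctl], 1)
  expect_equal(truth$k2_mult[i_top], 1 - 0.97)
  expect_equal(truth$kplus_mult[i_top], 1 - 0.29)
  # the generating params embedded in the traces carry the multipliers
  p_top <- ds$traces[[which.max(ds$doses)]][[1]]$meta$params
  p_ctl <- ds$traces[[which.min(ds$doses)]][[1]]$meta$params
  expect_equal(p_top$k_2 / p_ctl$k_2, 0.03, tolerance = 1e-12)
})

test_that("titration means converge to the hyperbola (CLT check)", {
  cfg <- generator_config(rng_seed = 8, n_reps = 1000)
  bt <- gen_fp_titration(cfg, K_D = 2e-6, B_max = 120, mp_noise_sd = 5)
  mu <- 120 * bt$fibril_concs / (2e-6 + bt$fibril_concs)
  se <- 5 / sqrt(1000)
  expect_true(all(abs(bt$delta_mP - mu) < 3 * se))
})

test_that("the library parses fully and its oracle is well-behaved", {
  lib <- shared_library()
  expect_identical(nrow(lib$library), 2000L)
  expect_identical(rownames(lib$features), lib$library$id)
  # hidden actives sit at the top of the landscape
  act <- lib$oracle(lib$actives)
  expect_true(all(act > 2.5))
  # a molecule far from every active reads ~1
  s <- tanimoto_matrix(lib$features, lib$features[lib$actives, , drop = FALSE])
  far_id <- lib$library$id[which.min(apply(s, 1, max))]
  expect_lt(abs(lib$oracle(far_id) - 1), 0.5)
  # repeated queries are deterministic
  expect_identical(lib$oracle(lib$library$id[1:5]),
                   lib$oracle(lib$library$id[1:5]))
})

test_that("the oracle is invariant under SMILES re-spelling", {
  lib <- shared_library()
  row <- lib$library[lib$library$family == "oxadiazole", ][1, ]
  v1 <- lib$oracle(row$id, row$smiles)
  # round-trip through the toolkit's canonical SMILES writer
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(row$smiles))
  can <- as.character(suppressWarnings(ChemmineR::sdf2smiles(sdf)))
  expect_false(identical(can, row$smiles))
  v2 <- lib$oracle(row$id, can)
  expect_identical(v1, v2)
})
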