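test_that("degenerate parameter sets give the closed-form limits", {
  tg <- seq(0, 1e5, by = 1000)
  # no nuclei, no seeds: nothing ever grows
  p0 <- rate_params(k_plus = 1e4, m_tot = 5e-6, M_0 = 0)
  expect_equal(simulate_aggregation(p0, tg)$signal, rep(0, length(tg)))
  # no elongation: mass cannot grow at all
  p1 <- rate_params(k_plus = 0, k_n = 1e-4, k_2 = 1e3, k_minus = 1e-6,
                    m_tot = 5e-6, M_0 = 5e-8)
  expect_equal(simulate_aggregation(p1, tg)$signal,
               rep(5e-8 / 5e-6, length(tg)), tolerance = 1e-9)
})

test_that("seeded early-time growth matches the analytic linear limit", {
  p <- rate_params(k_plus = 1e3, m_tot = 5e-6, M_0 = 5e-8)  # P_0 = 1e-10
  tg <- seq(0, 2000, by = 100)
  sim <- simulate_aggregation(p, tg)
  m0 <- p$m_tot - p$M_0
  analytic <- (p$M_0 + 2 * p$k_plus * m0 * p$P_0 * tg) / p$m_tot
  expect_lt(max(abs(sim$signal - analytic) / analytic), 1e-3)
})

test_that("adaptive solution matches a brute-force fixed-step integrator", {
  p <- default_kinetics("secondary")
  tg <- seq(0, 2e5, by = 900)
  sim <- simulate_aggregation(p, tg)
  oracle <- rk4_moments(p, 2e5, n_steps = 1e4)
  half <- (p$M_0 + p$m_tot) / 2
  t_pkg <- crossing_time(tg, sim$signal * p$m_tot, half)
  t_orc <- crossing_time(oracle$time, oracle$M, half)
  expect_lt(abs(t_pkg - t_orc) / t_orc, 0.005)
})

test_that("mass stays conserved, bounded and monotone across models", {
  tg <- seq(0, 2e5, by = 2000)
  cases <- list(default_kinetics("secondary"),
                default_kinetics("saturating"),
                default_kinetics("fragmentation"),
                rate_params(k_plus = 5e3, k_n = 1e-4, k_2 = 500,
                            k_minus = 1e-7, K_M = 2e-6,
                            m_tot = 8e-6, M_0 = 8e-8))
  for (p in cases) {
    sim <- simulate_aggregation(p, tg)
    M <- sim$signal * p$m_tot
    expect_true(all(M >= -1e-6 * p$m_tot))
    expect_true(all(M <= p$m_tot * (1 + 1e-6)))
    expect_true(all(diff(M) >= -1e-6 * p$m_tot))
  }
})

test_that("more seeds never slow the reaction down", {
  t12 <- vapply(c(1e-11, 1e-10, 1e-9, 5e-9), function(P0) {
    p <- rate_params(k_plus = 1e4, k_2 = 1750, m_tot = 5e-6, M_0 = 5e-8,
                     P_0 = P0)
    tr <- simulate_aggregation(p, seq(0, 3e5, by = 1800))
    crossing_time(tr$time, tr$signal, 0.5)
  }, numeric(1))
  expect_true(all(diff(t12) <= 0))
})

test_that("the unsaturated limit reproduces the plain secondary model", {
  tg <- seq(0, 2e5, by = 1800)
  p_inf <- default_kinetics("secondary")                 # K_M = Inf
  p_big <- update_params(p_inf, K_M = 10)                # 10 M >> 5 uM
  a <- simulate_aggregation(p_inf, tg)$signal
  b <- simulate_aggregation(p_big, tg)$signal
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("invalid parameter sets are rejected", {
  expect_error(rate_params(k_plus = -1), "non-negative")
  expect_error(rate_params(m_tot = 1e-6, M_0 = 2e-6), "seed mass")
  expect_error(rate_params(K_M = 0), "K_M")
  expect_error(rate_params(m_tot = 5e-6, M_0 = 5e-8, P_0 = 1e-7), "P_0")
  p <- default_kinetics("secondary")
  expect_error(simulate_aggregation(p, c(100, 200)), "start at 0")
  expect_error(simulate_aggregation(p, c(0, 100, 100)), "increasing")
})
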