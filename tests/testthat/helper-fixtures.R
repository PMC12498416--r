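# Shared fixtures, built once per test run.

# The synthetic screening library is expensive to featurize; memoize it.
shared_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(gen_library(generator_config(rng_seed = 42)))
    }
    cache
  }
})

# Fixed-step RK4 integrator for the two-moment system, independent of the
# package's adaptive solver; used as the brute-force oracle.
rk4_moments <- function(params, t_end, n_steps = 1e4) {
  h <- t_end / n_steps
  rhs <- function(s) {
    M <- min(s[2], params$m_tot)
    m <- max(params$m_tot - M, 0)
    sat <- if (is.finite(params$K_M)) 1 / (1 + (m / params$K_M)^params$n_2) else 1
    dP <- params$k_n * m^params$n_c +
      params$k_2 * m^params$n_2 * sat * M + params$k_minus * M
    dM <- 2 * params$k_plus * m * s[1]
    c(dP, dM)
  }
  s <- c(params$P_0, params$M_0)
  out <- matrix(NA_real_, n_steps + 1, 2)
  out[1, ] <- s
  for (i in seq_len(n_steps)) {
    k1 <- rhs(s); k2 <- rhs(s + h / 2 * k1)
    k3 <- rhs(s + h / 2 * k2); k4 <- rhs(s + h * k3)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1, ] <- s
  }
  list(time = seq(0, t_end, length.out = n_steps + 1), P = out[, 1],
       M = out[, 2])
}

# first linear-interpolated crossing of a level
crossing_time <- function(time, y, level) {
  i <- which(y >= level)[1]
  if (is.na(i) || i == 1) return(NA_real_)
  time[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) *
    (time[i] - time[i - 1])
}

# noise-free logistic trace
logistic_trace <- function(t50 = 36000, s = 4000, b = 100, p = 1100,
                           tmax = 1e5, by = 900) {
  tg <- seq(0, tmax, by = by)
  kinetic_trace(tg, b + (p - b) / (1 + exp(-(tg - t50) / s)))
}
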