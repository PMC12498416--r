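#' Synthetic-assay generator configuration
#'
#' Fixes every knob of the synthetic data generators: RNG seed, the ThT
#' signal map (signal = offset + gain * aggregate mass), the noise model,
#' the plate geometry, and the screening-library specification. A fixed
#' seed makes every generator bit-reproducible.
#'
#' @param rng_seed Integer seed.
#' @param noise_sd Additive Gaussian noise SD in AU (default 10).
#' @param noise_mult Multiplicative noise factor (SD of a lognormal gain
#'   jitter per read; default 0 = off).
#' @param offset Signal offset a in AU (default 50).
#' @param gain Signal gain b in AU per molar of aggregate mass
#'   (default 2e8, i.e. 1000 AU amplitude at 5 uM conversion).
#' @param read_interval Read spacing in seconds (default 900 = 15 min).
#' @param n_reps Replicates per condition (default 3).
#' @param library_size,n_actives,kernel_width,max_ratio,oracle_noise_sd
#'   Screening-library spec: library size (default 2000), number of
#'   hidden actives (8), activity kernel width on Tanimoto distance
#'   (0.15), maximum planted normalized half-time ratio (3), oracle
#'   measurement noise SD (0.1).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(rng_seed = 1, noise_sd = 10, noise_mult = 0,
                             offset = 50, gain = 2e8,
                             read_interval = 900, n_reps = 3,
                             library_size = 2000, n_actives = 8,
                             kernel_width = 0.15, max_ratio = 3,
                             oracle_noise_sd = 0.1) {
  stopifnot(noise_sd >= 0, noise_mult >= 0, n_reps >= 1)
  structure(list(rng_seed = rng_seed, noise_sd = noise_sd,
                 noise_mult = noise_mult, offset = offset, gain = gain,
                 read_interval = read_interval, n_reps = n_reps,
                 library_size = library_size, n_actives = n_actives,
                 kernel_width = kernel_width, max_ratio = max_ratio,
                 oracle_noise_sd = oracle_noise_sd),
            class = "generator_config")
}

#' Default rate constants of the synthetic assay
#'
#' Calibrated so that 5 uM monomer with 1% (50 nM) seeds is dominated by
#' secondary processes (seed elongation alone would take ~70 h to convert
#' the monomer) and reaches its half-time near 14-19 h under quiescent
#' conditions, matching the scale of seeded tau amplification assays.
#' Three model variants: "secondary" (monomer-dependent secondary
#' nucleation), "saturating" (secondary nucleation saturated at
#' K_M = 1 uM) and "fragmentation" (no secondary nucleation, fibril
#' breakage only), the last two sharing the gamma = -0.5 half-time
#' scaling limit.
#'
#' @param model One of "secondary", "saturating", "fragmentation".
#' @param m_tot,M_0 Condition concentrations (molar); seed number is
#'   M_0/500 by default.
#' @return A [rate_params()].
#' @export
default_kinetics <- function(model = c("secondary", "saturating",
                                       "fragmentation"),
                             m_tot = 5e-6, M_0 = 5e-8) {
  model <- match.arg(model)
  switch(model,
    secondary = rate_params(k_plus = 1e4, k_n = 1e-6, n_c = 2,
                            k_2 = 1750, n_2 = 2, m_tot = m_tot, M_0 = M_0),
    saturating = rate_params(k_plus = 1e4, k_n = 1e-6, n_c = 2,
                             k_2 = 1750, n_2 = 2, K_M = 1e-6,
                             m_tot = m_tot, M_0 = M_0),
    # fragmentation variant: lower k_plus so fragmentation amplification,
    # not elongation of the initial seed ends, dominates the half-time --
    # the regime in which the -0.5 half-time scaling emerges
    fragmentation = rate_params(k_plus = 300, k_n = 0, n_c = 2, k_2 = 0,
                                k_minus = 1.5e-6,
                                m_tot = m_tot, M_0 = M_0))
}

# simulate one condition and wrap in AU-scale noisy replicates
noisy_replicates <- function(config, params, time_grid, meta_base, well0) {
  sim <- simulate_aggregation(params, time_grid)
  M <- sim$signal * params$m_tot
  clean <- config$offset + config$gain * (M - params$M_0)
  lapply(seq_len(config$n_reps), function(r) {
    eps <- stats::rnorm(length(clean), 0, config$noise_sd)
    g <- if (config$noise_mult > 0)
      exp(stats::rnorm(1, 0, config$noise_mult)) else 1
    kinetic_trace(time_grid, config$offset + g * (clean - config$offset) + eps,
                  meta = c(meta_base,
                           list(replicate = r, well = well0 + r - 1,
                                params = params)))
  })
}

#' Generate a seeded monomer dilution series
#'
#' Emulates the seeded quiescent dilution-series assay: each monomer
#' concentration is seeded with 1% (mass) preformed fibrils, integrated
#' under the supplied kinetic model and read out as noisy ThT-like
#' fluorescence on the plate-reader grid.
#'
#' @param config A [generator_config()].
#' @param params Template [rate_params()]; per-condition m_tot/M_0/P_0 are
#'   overridden.
#' @param monomer_concs Molar monomer concentrations
#'   (default 3.2-15 uM, 6 levels).
#' @param seed_fraction Seed mass as a fraction of monomer (default 0.01).
#' @param duration Total time in seconds (default 60 h).
#' @return List of [kinetic_trace()]s (length = conditions x replicates)
#'   with the generating parameters in each trace's `meta$params`.
#' @export
gen_dilution_series <- function(config, params,
                                monomer_concs = c(3.2, 4, 6, 8, 12, 15) * 1e-6,
                                seed_fraction = 0.01,
                                duration = 60 * 3600) {
  set.seed(config$rng_seed)
  time_grid <- seq(0, duration, by = config$read_interval)
  out <- list()
  well <- 1L
  for (m0 in monomer_concs) {
    p <- update_params(params, m_tot = m0, M_0 = m0 * seed_fraction,
                       P_0 = m0 * seed_fraction / 500)
    trs <- noisy_replicates(config, p, time_grid,
                            list(monomer_uM = m0 * 1e6,
                                 seed_nM = m0 * seed_fraction * 1e9,
                                 compound = "none", compound_uM = 0),
                            well)
    well <- well + config$n_reps
    out <- c(out, trs)
  }
  out
}

# saturating dose law: fraction of the max-dose effect realized at dose d,
# h(0) = 0 and h(d_max) = 1 exactly
dose_effect_fraction <- function(dose, dose_max, shape = 0.5) {
  x <- dose / dose_max
  x * (1 + shape) / (x + shape)
}

#' Generate an inhibitor dose series with planted mechanism
#'
#' Emulates the 1x/2x/4x molar-equivalent dosing design: per-dose rate
#' constants are interpolated between the control values and the planted
#' maximum reductions by a saturating dose law that reaches the planted
#' reduction exactly at the top dose. Emits both the low-seed design
#' (secondary processes rate-limiting; default 5 uM monomer + 50 nM
#' seeds) and the high-seed elongation design (2.5 uM seeds + 5 uM
#' monomer).
#'
#' @param config A [generator_config()].
#' @param compound_id Compound label.
#' @param k2_reduction,kplus_reduction Planted fractional reductions of
#'   k_2 and k_plus at the top dose (0-1).
#' @param doses Molar doses including the 0 control
#'   (default c(0, 5, 10, 20) uM).
#' @param params Control-condition kinetics (default
#'   `default_kinetics("secondary")`).
#' @param duration_low,duration_high Trace lengths in seconds (defaults
#'   96 h and 24 h).
#' @return A [dose_series()] with `high_seed_traces` attached; planted
#'   truth in the `truth` attribute.
#' @export
gen_inhibitor_doses <- function(config, compound_id,
                                k2_reduction, kplus_reduction,
                                doses = c(0, 5, 10, 20) * 1e-6,
                                params = default_kinetics("secondary"),
                                duration_low = 96 * 3600,
                                duration_high = 24 * 3600) {
  set.seed(config$rng_seed + 1L)
  tg_low <- seq(0, duration_low, by = config$read_interval)
  tg_high <- seq(0, duration_high, by = config$read_interval)
  dmax <- max(doses)
  low <- list(); high <- list()
  truth <- data.frame(dose = doses, k2_mult = NA_real_, kplus_mult = NA_real_)
  well <- 1L
  for (i in seq_along(doses)) {
    h <- if (doses[i] == 0) 0 else dose_effect_fraction(doses[i], dmax)
    m2 <- 1 - k2_reduction * h
    mp <- 1 - kplus_reduction * h
    truth$k2_mult[i] <- m2; truth$kplus_mult[i] <- mp
    p_low <- update_params(params, k_2 = params$k_2 * m2,
                           k_plus = params$k_plus * mp)
    p_high <- update_params(p_low, m_tot = 7.5e-6, M_0 = 2.5e-6,
                            P_0 = 2.5e-6 / 500)
    meta <- list(compound = compound_id, compound_uM = doses[i] * 1e6,
                 monomer_uM = 5, seed_nM = 50)
    low[[i]] <- noisy_replicates(config, p_low, tg_low, meta, well)
    meta$seed_nM <- 2500
    high[[i]] <- noisy_replicates(config, p_high, tg_high, meta, well + 100L)
    well <- well + config$n_reps
  }
  ds <- dose_series(compound_id, doses, low, high_seed_traces = high)
  attr(ds, "truth") <- truth
  ds
}

#' Generate a normalized rate dose-response with a planted KIC50
#'
#' Plants a descending logistic on the approximate rate 1/t1/2
#' (vehicle = 100): half-times follow
#' t1/2(d) = t1/2(0) * (1 + (d/KIC50)^hill), with lognormal measurement
#' noise.
#'
#' @param config A [generator_config()].
#' @param kic50 Planted KIC50 (molar).
#' @param hill Hill slope (default 1.5).
#' @param doses Molar doses, no control (default 0.625-20 uM ladder).
#' @param control_half_time Vehicle half-time in seconds (default 19 h).
#' @param t12_cv Coefficient of variation of half-time noise
#'   (default 0.03).
#' @return List with `doses`, `half_times` (mean over replicates),
#'   `control_half_time`, `truth`.
#' @export
gen_rate_response <- function(config, kic50, hill = 1.5,
                              doses = c(0.625, 1.25, 2.5, 5, 10, 20) * 1e-6,
                              control_half_time = 19 * 3600,
                              t12_cv = 0.03) {
  set.seed(config$rng_seed + 2L)
  t12_true <- control_half_time * (1 + (doses / kic50)^hill)
  t12 <- vapply(t12_true, function(mu) {
    mean(mu * exp(stats::rnorm(config$n_reps, 0, t12_cv)))
  }, numeric(1))
  ctrl <- mean(control_half_time * exp(stats::rnorm(config$n_reps, 0, t12_cv)))
  list(doses = doses, half_times = t12, control_half_time = ctrl,
       truth = list(kic50 = kic50, hill = hill))
}

#' Generate a fluorescence-polarization titration with planted K_D
#'
#' Hyperbolic one-site signal plus Gaussian noise; replicate-averaged
#' ΔmP with per-level SD, as the binding module consumes.
#'
#' @param config A [generator_config()].
#' @param K_D Planted dissociation constant (molar).
#' @param B_max Saturating polarization change (mP, default 120).
#' @param fibril_concs Molar fibril concentrations, monomer equivalents
#'   (default two-fold ladder 0.156-10 uM).
#' @param mp_noise_sd Per-replicate noise SD in mP (default 3).
#' @param compound_id Label.
#' @return A [binding_titration()] with planted truth in attribute
#'   `truth`.
#' @export
gen_fp_titration <- function(config, K_D, B_max = 120,
                             fibril_concs = c(0.15625, 0.3125, 0.625, 1.25,
                                              2.5, 5, 10) * 1e-6,
                             mp_noise_sd = 3, compound_id = "cmpd") {
  set.seed(config$rng_seed + 3L)
  mu <- B_max * fibril_concs / (K_D + fibril_concs)
  reps <- vapply(mu, function(m)
    stats::rnorm(config$n_reps, m, mp_noise_sd), numeric(config$n_reps))
  reps <- matrix(reps, nrow = config$n_reps)
  bt <- binding_titration(compound_id, fibril_concs,
                          delta_mP = colMeans(reps),
                          sd = apply(reps, 2, stats::sd))
  attr(bt, "truth") <- list(K_D = K_D, B_max = B_max,
                            mp_noise_sd = mp_noise_sd)
  bt
}

# ---- screening library -------------------------------------------------

library_grammar <- function() {
  subs <- c("C", "CC", "CCC", "C(C)C", "C(C)(C)C", "C1CC1",
            "c1ccccc1", "c1ccc(F)cc1", "c1ccc(Cl)cc1", "c1ccc(C)cc1",
            "c1ccc(OC)cc1", "c1ccc(cc1)O", "c1ccc(cc1)C(F)(F)F",
            "c1ccncc1", "c1ccc(cn1)C", "c1ccsc1", "c1cc[nH]c1",
            "C1CCCCC1", "CO", "CCO")
  templates <- c(
    oxadiazole  = "%sc1nnc(%s)o1",
    amide       = "%sC(=O)N%s",
    sulfonamide = "%sS(=O)(=O)N%s",
    urea        = "%sNC(=O)N%s",
    ester       = "%sOC(=O)%s")
  list(subs = subs, templates = templates)
}

#' Generate the synthetic screening library and its assay oracle
#'
#' Enumerates valid SMILES from a combinatorial scaffold-substituent
#' grammar (five linker scaffolds, including a 1,3,4-oxadiazole family,
#' each decorated with two substituents from a 20-fragment set), plants
#' hidden actives inside the oxadiazole family, and returns an assay
#' oracle with a smooth structure-activity landscape: the oracle's
#' normalized half-time for a molecule is
#' 1 + (max_ratio - 1) * exp(-d^2 / w^2) + noise, where d is the Tanimoto
#' distance of the molecule's fingerprint to the nearest hidden active.
#' Oracle noise is drawn from an RNG seeded by the fingerprint itself, so
#' repeated queries and re-canonicalized SMILES give identical values.
#'
#' @param config A [generator_config()]; `library_size`, `n_actives`,
#'   `kernel_width`, `max_ratio` and `oracle_noise_sd` are honoured.
#' @return List with `library` (data.frame id, smiles, family),
#'   `features` (fingerprint matrix), `actives` (ids of hidden actives),
#'   and `oracle` (function(ids, smiles) -> normalized half-times).
#' @export
gen_library <- function(config) {
  g <- library_grammar()
  grid <- expand.grid(tpl = names(g$templates), r1 = g$subs, r2 = g$subs,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$tpl, grid$r1, grid$r2), ]
  smiles <- sprintf(g$templates[grid$tpl], grid$r1, grid$r2)
  keep <- !duplicated(smiles)
  grid <- grid[keep, ]; smiles <- smiles[keep]
  if (nrow(grid) > config$library_size) {
    set.seed(config$rng_seed + 4L)
    # keep every oxadiazole; sample the remainder down to size
    ox <- which(grid$tpl == "oxadiazole")
    other <- setdiff(seq_len(nrow(grid)), ox)
    take <- sort(c(ox, sample(other, config$library_size - length(ox))))
    grid <- grid[take, ]; smiles <- smiles[take]
  }
  ids <- sprintf("Z%04d", seq_along(smiles))
  f <- featurize(smiles, ids)
  stopifnot(nrow(f$rejected) == 0)
  fp <- f$features

  set.seed(config$rng_seed + 5L)
  ox_ids <- ids[grid$tpl == "oxadiazole"]
  actives <- sort(sample(ox_ids, config$n_actives))
  active_fp <- fp[actives, , drop = FALSE]
  w <- config$kernel_width; mr <- config$max_ratio
  ns <- config$oracle_noise_sd; seed0 <- config$rng_seed

  oracle <- function(q_ids, q_smiles = NULL) {
    qfp <- if (!is.null(q_smiles)) {
      featurize(as.character(q_smiles), as.character(q_ids))$features
    } else fp[q_ids, , drop = FALSE]
    s <- tanimoto_matrix(qfp, active_fp)
    d <- 1 - apply(s, 1, max)
    base <- 1 + (mr - 1) * exp(-d^2 / w^2)
    noise <- vapply(seq_len(nrow(qfp)), function(i) {
      h <- sum(which(qfp[i, ] == 1L)) %% 1000003L
      set.seed((seed0 * 7919L + h) %% .Machine$integer.max)
      stats::rnorm(1, 0, ns)
    }, numeric(1))
    unname(base + noise)
  }

  list(library = data.frame(id = ids, smiles = smiles, family = grid$tpl,
                            stringsAsFactors = FALSE),
       features = fp, actives = actives, oracle = oracle)
}
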