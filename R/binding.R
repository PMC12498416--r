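#' Fluorescence-polarization binding titration
#'
#' A fixed ligand concentration titrated with increasing fibril
#' concentrations (monomer equivalents), recording the change in
#' fluorescence polarization.
#'
#' @param compound_id Character id.
#' @param fibril_concs Fibril concentrations in molar (monomer
#'   equivalents), non-negative and strictly increasing; >= 4 levels.
#' @param delta_mP Polarization change (mP) per level (means over
#'   replicates).
#' @param sd Optional per-level SD of `delta_mP`.
#' @param ligand_conc Ligand concentration in molar (default 10 uM).
#' @return Object of class `binding_titration`.
#' @export
binding_titration <- function(compound_id, fibril_concs, delta_mP,
                              sd = NULL, ligand_conc = 10e-6) {
  fibril_concs <- as.numeric(fibril_concs)
  if (length(fibril_concs) < 4) stop("need >= 4 fibril concentration levels")
  if (any(fibril_concs < 0) || any(diff(fibril_concs) <= 0)) {
    stop("fibril_concs must be non-negative and strictly increasing")
  }
  if (length(delta_mP) != length(fibril_concs) || any(!is.finite(delta_mP))) {
    stop("delta_mP must be finite, one value per concentration")
  }
  structure(list(compound_id = compound_id, fibril_concs = fibril_concs,
                 delta_mP = as.numeric(delta_mP), sd = sd,
                 ligand_conc = ligand_conc),
            class = "binding_titration")
}

#' One-site binding fit of an FP titration
#'
#' Fits the hyperbolic one-step binding curve
#' \eqn{\Delta mP = B_{max} [F] / (K_D + [F])} by least squares and
#' returns K_D and B_max with asymptotic standard deviations. Fibril
#' concentration is in monomer equivalents; binding-site multiplicity is
#' folded into B_max. A quadratic ligand-depletion variant (exact bound
#' fraction at finite ligand concentration) is available via
#' `depletion = TRUE`.
#'
#' The fit is flagged poorly determined when the titration shows no
#' saturation evidence (max signal < 2 x signal at the lowest non-zero
#' concentration, or K_D beyond the titrated range, or SD(K_D) comparable
#' to the estimate).
#'
#' @param titration A [binding_titration()].
#' @param depletion Use the ligand-depletion (quadratic) form.
#' @return List with `K_D`, `B_max` (molar, mP), `K_D_sd`, `B_max_sd`,
#'   `poorly_determined` flag and the `nls` fit object.
#' @export
fit_one_site_binding <- function(titration, depletion = FALSE) {
  stopifnot(inherits(titration, "binding_titration"))
  F_ <- titration$fibril_concs; y <- titration$delta_mP
  dat <- data.frame(F_ = F_, y = y)
  kd0 <- max(stats::median(F_), 1e-9)
  b0 <- max(y) * 1.2
  if (depletion) {
    L <- titration$ligand_conc
    fit <- minpack.lm::nlsLM(
      y ~ Bmax * ((L + F_ + KD) - sqrt((L + F_ + KD)^2 - 4 * L * F_)) / (2 * L),
      data = dat, start = list(KD = kd0, Bmax = b0),
      lower = c(1e-12, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  } else {
    fit <- minpack.lm::nlsLM(
      y ~ Bmax * F_ / (KD + F_), data = dat,
      start = list(KD = kd0, Bmax = b0), lower = c(1e-12, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
  }
  cf <- stats::coef(fit)
  sds <- tryCatch(sqrt(diag(stats::vcov(fit))),
                  error = function(e) c(KD = NA_real_, Bmax = NA_real_))
  lowest <- y[which(F_ > 0)[1]]
  no_saturation <- is.finite(lowest) && lowest > 0 && max(y) < 2 * lowest
  # poorly determined when the titration does not bracket the affinity:
  # the 95% interval for K_D extends past the highest fibril
  # concentration, or the SD is of the order of the estimate itself
  unbracketed <- is.finite(sds[["KD"]]) &&
    cf[["KD"]] + 2 * sds[["KD"]] > max(F_)
  poorly <- no_saturation || cf[["KD"]] > max(F_) || unbracketed ||
    (is.finite(sds[["KD"]]) && sds[["KD"]] >= 0.5 * cf[["KD"]])
  list(K_D = unname(cf[["KD"]]), B_max = unname(cf[["Bmax"]]),
       K_D_sd = unname(sds[["KD"]]), B_max_sd = unname(sds[["Bmax"]]),
       poorly_determined = poorly, fit = fit)
}
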