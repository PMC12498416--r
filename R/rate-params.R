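#' Kinetic rate parameters for one aggregation condition
#'
#' Bundles the microscopic rate constants and reaction orders of the
#' two-moment aggregation model together with the condition-specific
#' concentrations (total monomer-equivalent protein, initial seed mass and
#' seed number). All quantities are in SI molar units and seconds.
#'
#' @param k_plus Elongation rate constant (per molar per second).
#' @param k_n Primary nucleation rate constant (M^(1-n_c) per second).
#' @param n_c Primary nucleation reaction order (dimensionless, >= 0).
#' @param k_2 Secondary nucleation rate constant (M^(-n_2) per second).
#' @param n_2 Secondary nucleation reaction order (dimensionless, >= 0).
#' @param K_M Saturation constant of secondary nucleation (molar);
#'   `Inf` gives the plain (unsaturated) secondary-nucleation model.
#' @param k_minus Fragmentation rate constant (per second).
#' @param m_tot Total monomer-equivalent protein concentration (molar),
#'   free monomer plus seed mass.
#' @param M_0 Initial seed mass concentration (molar, monomer equivalents).
#' @param P_0 Initial seed number concentration (molar). Defaults to
#'   `M_0 / seed_length`, i.e. seeds of a given mean length in monomers.
#' @param seed_length Mean seed length in monomer units, used only when
#'   `P_0` is not supplied. Default 500.
#'
#' @return An object of class `rate_params` (a named list).
#' @examples
#' rate_params(k_plus = 1e6, k_2 = 17.5, m_tot = 5e-6, M_0 = 5e-8)
#' @export
rate_params <- function(k_plus = 0, k_n = 0, n_c = 2, k_2 = 0, n_2 = 2,
                        K_M = Inf, k_minus = 0,
                        m_tot = 5e-6, M_0 = 0, P_0 = NULL,
                        seed_length = 500) {
  if (is.null(P_0)) P_0 <- if (M_0 > 0) M_0 / seed_length else 0
  p <- list(k_plus = k_plus, k_n = k_n, n_c = n_c, k_2 = k_2, n_2 = n_2,
            K_M = K_M, k_minus = k_minus,
            m_tot = m_tot, M_0 = M_0, P_0 = P_0)
  validate_rate_params(p)
  structure(p, class = "rate_params")
}

validate_rate_params <- function(p) {
  nonneg <- c("k_plus", "k_n", "n_c", "k_2", "n_2", "k_minus",
              "m_tot", "M_0", "P_0")
  for (f in nonneg) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || is.na(p[[f]]) ||
        p[[f]] < 0) {
      stop("rate_params: `", f, "` must be a single non-negative number")
    }
  }
  if (!(p$K_M > 0)) stop("rate_params: `K_M` must be positive (Inf allowed)")
  if (p$M_0 > p$m_tot) stop("rate_params: seed mass M_0 exceeds m_tot")
  if (p$P_0 > p$M_0 && p$P_0 > 0) {
    stop("rate_params: P_0 exceeds M_0 (a fibril contains >= 1 monomer)")
  }
  invisible(p)
}

#' @export
print.rate_params <- function(x, ...) {
  cat("<rate_params>\n")
  cat(sprintf("  k+ = %.3g /M/s   kn = %.3g   n_c = %g\n",
              x$k_plus, x$k_n, x$n_c))
  cat(sprintf("  k2 = %.3g /M^n2/s   n_2 = %g   K_M = %.3g M   k- = %.3g /s\n",
              x$k_2, x$n_2, x$K_M, x$k_minus))
  cat(sprintf("  m_tot = %.3g M   M0 = %.3g M   P0 = %.3g M\n",
              x$m_tot, x$M_0, x$P_0))
  invisible(x)
}

#' Replace fields of a rate-parameter set
#'
#' @param params A `rate_params` object.
#' @param ... Named fields to replace (same names as [rate_params()]).
#' @return A new validated `rate_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "rate_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) stop("unknown rate_params field(s): ",
                        paste(bad, collapse = ", "))
  params[names(repl)] <- repl
  validate_rate_params(params)
  structure(params, class = "rate_params")
}
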