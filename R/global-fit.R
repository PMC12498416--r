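#' Global fit of the moment model across a set of traces
#'
#' Fits a shared subset of rate constants jointly to several normalized
#' kinetic traces (e.g. a monomer dilution series), each trace keeping its
#' own condition-specific concentrations (m_tot, M_0, P_0). The misfit is
#' the summed squared residual between the observed normalized signal and
#' the model's normalized aggregate mass (M - M_0)/(m_tot - M_0).
#' Optimization is multi-start Levenberg-Marquardt on log-parameters:
#' the first start is the supplied parameter set, the remaining starts are
#' drawn log-uniformly within the bounds under a fixed, recorded RNG seed.
#'
#' @param traces List of [kinetic_trace()]s with signal on the normalized
#'   (mass-fraction) scale in [0, 1] and a `rate_params` object in
#'   `meta$params` carrying that trace's m_tot, M_0, P_0.
#' @param params A [rate_params()] giving every fixed constant and the
#'   starting value of every free one. Reaction orders are always fixed.
#' @param free Character vector naming the constants to fit; any of
#'   "k_plus", "k_n", "k_2", "k_minus", "K_M". May be empty, in which case
#'   the misfit of `params` is computed with no optimization.
#' @param lower,upper Named numeric vectors of bounds for the free
#'   constants (natural scale). Default: start / 1e3 to start * 1e3.
#' @param n_starts Number of Levenberg-Marquardt starts (default 20).
#' @param seed RNG seed used to draw the extra starts (recorded in output).
#' @return List with `params` (fitted `rate_params`, condition fields from
#'   the first trace), `estimates` (named free constants), `per_trace_ssr`,
#'   `total_ssr`, `n_starts`, `seed`, `start_ssr` (best misfit per start)
#'   and `converged`.
#' @export
global_fit <- function(traces, params, free = c("k_plus", "k_2"),
                       lower = NULL, upper = NULL,
                       n_starts = 20, seed = 1) {
  stopifnot(inherits(params, "rate_params"), length(traces) >= 1)
  allowed <- c("k_plus", "k_n", "k_2", "k_minus", "K_M")
  if (length(free) && !all(free %in% allowed)) {
    stop("free must be a subset of: ", paste(allowed, collapse = ", "))
  }
  cond <- lapply(traces, function(tr) {
    cp <- tr$meta$params
    if (is.null(cp)) stop("each trace needs meta$params with m_tot, M_0, P_0")
    cp
  })

  resid_fun <- function(theta_log) {
    vals <- 10^theta_log
    unlist(lapply(seq_along(traces), function(i) {
      p <- cond[[i]]
      for (j in seq_along(free)) p[[free[j]]] <- vals[j]
      # shared fixed constants come from `params`
      for (f in setdiff(allowed, free)) p[[f]] <- params[[f]]
      p$n_c <- params$n_c; p$n_2 <- params$n_2
      tr <- traces[[i]]
      sim <- tryCatch(
        simulate_aggregation(structure(p, class = "rate_params"), tr$time),
        error = function(e) NULL)
      if (is.null(sim)) return(rep(1e3, length(tr$time)))
      denom <- p$m_tot - p$M_0
      pred <- if (denom > 0) (sim$signal * p$m_tot - p$M_0) / denom
              else sim$signal
      tr$signal - pred
    }))
  }

  if (length(free) == 0) {
    res <- resid_fun(numeric(0))
    ssr <- per_trace_ssr(res, traces)
    return(list(params = params, estimates = stats::setNames(numeric(0), free),
                per_trace_ssr = ssr, total_ssr = sum(ssr),
                n_starts = 0L, seed = seed, start_ssr = numeric(0),
                converged = TRUE))
  }

  start0 <- vapply(free, function(f) params[[f]], numeric(1))
  if (any(start0 <= 0)) stop("free constants need positive starting values")
  if (is.null(lower)) lower <- start0 / 1e3
  if (is.null(upper)) upper <- start0 * 1e3
  lower <- lower[free]; upper <- upper[free]
  llo <- log10(lower); lup <- log10(upper)

  starts <- matrix(log10(start0), nrow = 1)
  if (n_starts > 1) {
    rs <- local({
      set.seed(seed)
      matrix(stats::runif((n_starts - 1) * length(free), rep(llo, each = n_starts - 1),
                          rep(lup, each = n_starts - 1)),
             nrow = n_starts - 1)
    })
    starts <- rbind(starts, rs)
  }

  best <- NULL; start_ssr <- rep(NA_real_, nrow(starts))
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[s, ], fn = resid_fun,
                         lower = llo, upper = lup,
                         control = minpack.lm::nls.lm.control(maxiter = 150)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr_s <- sum(fit$fvec^2)
    start_ssr[s] <- ssr_s
    if (is.null(best) || ssr_s < sum(best$fvec^2)) best <- fit
  }
  if (is.null(best)) stop("global fit failed to converge from any start")

  est <- stats::setNames(10^best$par, free)
  at_bound <- est <= lower * 1.001 | est >= upper * 0.999
  if (any(at_bound)) {
    warning("fitted constant(s) at imposed bound: ",
            paste(free[at_bound], collapse = ", "))
  }
  res <- best$fvec
  ssr <- per_trace_ssr(res, traces)
  out_params <- cond[[1]]
  for (j in seq_along(free)) out_params[[free[j]]] <- est[[j]]
  for (f in setdiff(allowed, free)) out_params[[f]] <- params[[f]]
  out_params$n_c <- params$n_c; out_params$n_2 <- params$n_2
  list(params = structure(out_params, class = "rate_params"),
       estimates = est,
       per_trace_ssr = ssr, total_ssr = sum(ssr),
       n_starts = n_starts, seed = seed, start_ssr = start_ssr,
       converged = best$info %in% 1:4, at_bound = at_bound)
}

per_trace_ssr <- function(res, traces) {
  lens <- vapply(traces, function(tr) length(tr$time), integer(1))
  idx <- rep(seq_along(traces), lens)
  as.numeric(tapply(res^2, idx, sum))
}
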