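#' Extract the aggregation half-time from a kinetic trace
#'
#' Fits a four-parameter logistic (baseline, plateau, midpoint, slope) to
#' the raw signal and reports the fitted midpoint as the half-time, the
#' time at which half of the amplitude between baseline and plateau is
#' reached. Traces whose amplitude is indistinguishable from noise
#' (plateau - baseline < 5 x estimated noise SD) are classified as
#' "no aggregation" and get `half_time = NA` with `flag = "no_aggregation"`.
#' Traces that have not plateaued by the last read return a flagged
#' estimate with a warning.
#'
#' @param trace A [kinetic_trace()].
#' @return The input trace with `fitted_baseline`, `fitted_plateau` and
#'   `half_time` set, plus attribute fields in `$fit`:
#'   `flag` (one of "ok", "no_aggregation", "incomplete"),
#'   `slope_s` (logistic time constant, seconds) and `noise_sd`.
#' @examples
#' p <- rate_params(k_plus = 1e6, k_2 = 17.5, m_tot = 5e-6, M_0 = 5e-8)
#' tr <- simulate_aggregation(p, seq(0, 2e5, by = 900))
#' extract_half_time(tr)$half_time / 3600   # hours
#' @export
extract_half_time <- function(trace) {
  stopifnot(inherits(trace, "kinetic_trace"))
  t <- trace$time; y <- trace$signal
  # noise estimate from first differences, robust to the sigmoid trend
  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  base0 <- stats::median(y[seq_len(max(3, ceiling(length(y) * 0.05)))])
  plat0 <- stats::median(y[seq(length(y) - max(2, ceiling(length(y) * 0.05) - 1),
                               length(y))])
  amp <- max(y) - min(y)
  if (amp < 5 * max(noise_sd, .Machine$double.eps) || amp == 0) {
    trace$fit <- list(flag = "no_aggregation", noise_sd = noise_sd)
    trace$half_time <- NA_real_
    return(trace)
  }
  # crossing-based start for the midpoint
  half_level <- (base0 + plat0) / 2
  above <- y >= half_level
  i <- which(above)[1]
  t50_0 <- if (is.na(i) || i == 1) stats::median(t) else {
    t[i - 1] + (half_level - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  }
  s0 <- diff(range(t)) / 20
  dat <- data.frame(t = t, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + (p - b) / (1 + exp(-(t - t50) / s)),
      data = dat,
      start = list(b = base0, p = plat0, t50 = t50_0, s = s0),
      lower = c(-Inf, -Inf, 0, diff(range(t)) * 1e-5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the level crossing of the raw trace
    trace$fitted_baseline <- base0
    trace$fitted_plateau <- plat0
    trace$half_time <- t50_0
    trace$fit <- list(flag = "crossing_fallback", noise_sd = noise_sd)
    return(trace)
  }
  cf <- stats::coef(fit)
  flag <- "ok"
  # plateau not reached: midpoint beyond 90% of the observed span
  if (cf[["t50"]] > 0.9 * max(t) || max(y) < cf[["b"]] +
      0.9 * (cf[["p"]] - cf[["b"]])) {
    flag <- "incomplete"
    warning("transition incomplete at end of trace; half-time is an extrapolated estimate")
  }
  # baseline/plateau from the flat phases themselves: the symmetric
  # logistic locates the transition but its asymptotes are biased on
  # asymmetric aggregation curves
  pre <- y[t <= cf[["t50"]] - 4 * cf[["s"]]]
  post <- y[t >= cf[["t50"]] + 4 * cf[["s"]]]
  b_hat <- if (length(pre) >= 3 && flag == "ok") stats::median(pre)
           else unname(cf[["b"]])
  p_hat <- if (length(post) >= 3 && flag == "ok") stats::median(post)
           else unname(cf[["p"]])
  trace$fitted_baseline <- b_hat
  trace$fitted_plateau <- p_hat
  trace$half_time <- unname(cf[["t50"]])
  trace$fit <- list(flag = flag, slope_s = unname(cf[["s"]]),
                    noise_sd = noise_sd)
  trace
}

#' Half-time of a trace as a number
#'
#' Convenience wrapper around [extract_half_time()] returning just the
#' half-time in seconds (NA for "no aggregation").
#' @param trace A [kinetic_trace()].
#' @return Half-time in seconds, or NA.
#' @export
half_time <- function(trace) extract_half_time(trace)$half_time

#' Normalize a trace to mass-fraction scale
#'
#' Maps the fitted baseline to 0 and the fitted plateau to 1.
#' @param trace A [kinetic_trace()]; fitted fields are computed if absent.
#' @return A `kinetic_trace` with normalized signal.
#' @export
normalize_trace <- function(trace) {
  if (is.na(trace$fitted_baseline) || is.na(trace$fitted_plateau)) {
    trace <- extract_half_time(trace)
  }
  b <- trace$fitted_baseline; p <- trace$fitted_plateau
  if (is.na(b) || is.na(p) || p <= b) stop("cannot normalize: no amplitude")
  trace$signal <- (trace$signal - b) / (p - b)
  trace$fitted_baseline <- 0; trace$fitted_plateau <- 1
  trace
}

robust_baseline <- function(trace) {
  t <- trace$time; y <- trace$signal
  n <- length(y)
  # pre-transition window: reads before 70% of the 10%-amplitude crossing
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  amp <- max(ys) - min(ys)
  i_cross <- which(ys >= min(ys) + 0.1 * amp)[1]
  t_win <- 0.7 * t[max(i_cross, 2)]
  idx <- which(t <= t_win)
  if (length(idx) < 4) idx <- seq_len(min(4, n))
  if (length(idx) > 60) idx <- idx[seq_len(60)]
  t0 <- t[idx]; y0 <- y[idx]
  # early seeded growth is ~quadratic in t; a quadratic intercept is
  # unbiased to leading order, but needs enough points to be stable
  cf <- if (length(idx) >= 6) {
    stats::coef(stats::lm(y0 ~ t0 + I(t0^2)))
  } else stats::coef(stats::lm(y0 ~ t0))
  unname(cf[1])
}

trace_plateau <- function(trace) {
  n <- length(trace$time)
  tail_idx <- seq(ceiling(n * 0.85), n)
  tt <- trace$time[tail_idx]; yy <- trace$signal[tail_idx]
  slope <- unname(stats::coef(stats::lm(yy ~ tt))[2])
  level <- stats::median(yy)
  amp <- level - min(trace$signal)
  converged <- amp > 0 && abs(slope) * diff(range(tt)) < 0.02 * amp
  list(level = level, converged = converged)
}

#' Normalize a plate of traces through a shared fluorescence gain
#'
#' Converts raw-AU traces to the normalized aggregate-mass scale
#' ((M - M_0)/(m_tot - M_0)) without requiring every well to plateau:
#' each well's baseline is the extrapolated signal at t = 0, and the
#' common gain (AU per molar of converted mass) is estimated from the
#' reference wells that have demonstrably plateaued, divided by their
#' convertible mass m_tot - M_0 (from `meta$params`). Wells that never
#' reach plateau (strong inhibition, low concentration, high-seed
#' designs) are then normalized consistently through the shared gain.
#'
#' @param traces List of [kinetic_trace()]s with `meta$params`.
#' @param ref Indices of traces eligible for gain estimation (default:
#'   all); only those whose tail is flat are actually used.
#' @return List of normalized traces (same order).
#' @export
normalize_plate <- function(traces, ref = seq_along(traces)) {
  base <- vapply(traces, robust_baseline, numeric(1))
  gains <- c()
  for (i in ref) {
    pl <- trace_plateau(traces[[i]])
    pp <- traces[[i]]$meta$params
    if (is.null(pp)) stop("normalize_plate needs meta$params in each trace")
    if (pl$converged) {
      gains <- c(gains, (pl$level - base[i]) / (pp$m_tot - pp$M_0))
    }
  }
  if (!length(gains)) stop("no reference trace has plateaued; cannot fix the gain")
  gain <- stats::median(gains)
  lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    pp <- tr$meta$params
    tr$signal <- (tr$signal - base[i]) / (gain * (pp$m_tot - pp$M_0))
    tr
  })
}

#' Half-time scaling exponent over a monomer dilution series
#'
#' Fits a power law t1/2 = C * m0^gamma by least squares on the
#' double-logarithmic scale and returns the exponent gamma with its
#' standard error. Gamma near -0.5 indicates aggregation dominated by
#' secondary processes (fragmentation or saturated secondary nucleation);
#' steeper exponents indicate monomer-dependent secondary nucleation.
#'
#' @param half_times Half-times in seconds, one per concentration
#'   (replicates may be supplied; pair each with its concentration).
#' @param monomer_concs Matching monomer concentrations (molar).
#' @return List with `gamma`, `se`, `intercept` and the underlying `lm` fit.
#' @export
scaling_exponent <- function(half_times, monomer_concs) {
  if (length(half_times) != length(monomer_concs)) {
    stop("half_times and monomer_concs must have equal length")
  }
  if (length(unique(monomer_concs)) < 3) {
    stop("need half-times at >= 3 distinct concentrations")
  }
  if (any(!is.finite(half_times)) || any(half_times <= 0)) {
    stop("all half-times must be finite and positive")
  }
  fit <- stats::lm(log(half_times) ~ log(monomer_concs))
  sm <- summary(fit)$coefficients
  list(gamma = unname(sm[2, 1]), se = unname(sm[2, 2]),
       intercept = unname(sm[1, 1]), fit = fit)
}
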