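#' Inhibitor dose series
#'
#' Bundles kinetic traces for one compound at several doses (including the
#' vehicle control at dose 0), for low-seed (secondary-process) and
#' optionally high-seed (elongation) assay designs.
#'
#' @param compound_id Character id.
#' @param doses Numeric doses in molar, unique and non-negative; must
#'   contain exactly one 0 (the vehicle control).
#' @param traces List (one element per dose, same order) of lists of
#'   [kinetic_trace()] replicates (low-seed design).
#' @param high_seed_traces Optional list like `traces` from the high-seed
#'   elongation design.
#' @return An object of class `dose_series`.
#' @export
dose_series <- function(compound_id, doses, traces,
                        high_seed_traces = NULL) {
  doses <- as.numeric(doses)
  if (any(doses < 0) || anyDuplicated(doses)) {
    stop("doses must be unique and non-negative")
  }
  if (sum(doses == 0) != 1) stop("exactly one dose must be the 0 control")
  if (length(traces) != length(doses)) stop("one trace set per dose required")
  structure(list(compound_id = compound_id, doses = doses, traces = traces,
                 high_seed_traces = high_seed_traces),
            class = "dose_series")
}

#' Normalized half-time of a compound trace against its control
#'
#' The primary potency metric of the aggregation screen: the ratio of the
#' compound well's half-time to the vehicle-control half-time. Ratios > 1
#' indicate inhibition, < 1 induction.
#'
#' @param trace Compound-well [kinetic_trace()].
#' @param control Vehicle-control [kinetic_trace()].
#' @return Dimensionless ratio.
#' @export
normalized_half_time <- function(trace, control) {
  tc <- extract_half_time(control)
  if (is.na(tc$half_time)) stop("invalid assay: control shows no aggregation")
  tt <- extract_half_time(trace)
  if (is.na(tt$half_time)) return(Inf)   # full arrest: unbounded extension
  tt$half_time / tc$half_time
}

#' Classify a normalized half-time into screen categories
#'
#' Strict thresholds: ratio > 2 is highly potent, ratio > 1.5 is potent
#' (a "hit"), ratio below 1 by more than `inducer_margin` is an inducer,
#' anything else inactive.
#'
#' @param ratio Normalized half-time (finite or Inf).
#' @param inducer_margin How far below 1 counts as induction (default 0.1).
#' @return One of "inactive", "potent", "highly_potent", "inducer".
#' @export
classify_hit <- function(ratio, inducer_margin = 0.1) {
  vapply(ratio, function(r) {
    if (is.na(r)) stop("classify_hit: ratio must not be NA")
    if (r > 2) "highly_potent"
    else if (r > 1.5) "potent"
    else if (r < 1 - inducer_margin) "inducer"
    else "inactive"
  }, character(1))
}

#' Is a normalized half-time a screening hit?
#' @param ratio Normalized half-time.
#' @return Logical: TRUE for "potent" or "highly_potent".
#' @export
is_hit <- function(ratio) ratio > 1.5

#' Normalize a dose series to mass-fraction scale via its control
#'
#' Inhibited wells need not plateau within the assay, so per-trace
#' normalization is impossible; instead the vehicle control's fitted
#' baseline and plateau define the shared signal map (all wells see the
#' same fluorophore gain), and every trace is mapped through it. High-seed
#' traces are scaled by the ratio of convertible mass
#' (m_tot - M_0) between the high-seed and low-seed designs, read from
#' each trace's `meta$params`.
#'
#' @param series A [dose_series()] of raw-AU traces.
#' @return The series with all traces on the normalized scale where the
#'   control baseline is 0 and full conversion is 1.
#' @export
normalize_dose_series <- function(series) {
  stopifnot(inherits(series, "dose_series"))
  i0 <- which(series$doses == 0)
  flat <- unlist(series$traces, recursive = FALSE)
  n_per <- vapply(series$traces, length, integer(1))
  ref <- which(rep(seq_along(series$doses), n_per) == i0)
  norm_low <- normalize_plate(flat, ref = ref)
  series$traces <- split(norm_low, rep(seq_along(series$doses), n_per))
  if (!is.null(series$high_seed_traces)) {
    n_h <- vapply(series$high_seed_traces, length, integer(1))
    # high-seed wells never plateau: borrow the gain via the low-seed
    # control by normalizing jointly
    joint <- c(flat[ref], unlist(series$high_seed_traces, recursive = FALSE))
    norm_j <- normalize_plate(joint, ref = seq_along(ref))
    series$high_seed_traces <- split(norm_j[-seq_along(ref)],
                                     rep(seq_along(series$high_seed_traces), n_h))
  }
  series
}

#' Deconvolve inhibitor mechanism from a dose series
#'
#' Quantifies how a compound perturbs the microscopic rate constants.
#' The vehicle control is fitted first (constants in `free` floating,
#' starting from `baseline_params`) to pin the assay's baseline constants;
#' each non-zero dose is then refitted with only `free` floating and every
#' other constant held at the control value. Fractional reductions are
#' 1 - k(dose)/k(control). If the series carries high-seed traces, k_plus
#' at each dose is estimated from the high-seed design (where elongation
#' dominates) and the low-seed refit floats k_2 alone; otherwise the
#' requested constants are refitted jointly on the low-seed traces.
#'
#' @param series A [dose_series()] of normalized (mass-fraction) traces.
#' @param baseline_params [rate_params()] starting values for the control
#'   fit; condition fields (m_tot, M_0, P_0) come from each trace's meta.
#' @param free Constants to attribute the effect to: subset of
#'   c("k_2", "k_plus"). Default both.
#' @param n_starts Multi-start count for the control fit (dose refits reuse
#'   the control optimum as start). Default 5.
#' @param seed RNG seed for the multi-start draws.
#' @return A `mechanism_report`: list with `compound_id`, `doses`,
#'   `constants` (per-dose data.frame of fitted k_2/k_plus),
#'   `delta_k2`, `delta_kplus` (fractional reductions at the highest dose),
#'   `elongation_slopes` (AU/s per dose, if high-seed traces present).
#' @export
fit_dose_mechanism <- function(series, baseline_params,
                               free = c("k_2", "k_plus"),
                               n_starts = 5, seed = 1) {
  stopifnot(inherits(series, "dose_series"))
  free <- match.arg(free, c("k_2", "k_plus"), several.ok = TRUE)
  ord <- order(series$doses)
  doses <- series$doses[ord]
  lowseed <- series$traces[ord]
  highseed <- if (!is.null(series$high_seed_traces))
    series$high_seed_traces[ord] else NULL
  use_highseed <- !is.null(highseed) && "k_plus" %in% free

  # which constants float on the low-seed traces
  low_free <- if (use_highseed) setdiff(free, "k_plus") else free

  fit_kplus_high <- function(trs, start_params) {
    gf <- global_fit(trs, start_params, free = "k_plus",
                     n_starts = n_starts, seed = seed)
    gf$estimates[["k_plus"]]
  }

  # --- control (dose 0) ---
  ctrl_par <- baseline_params
  if (use_highseed) {
    kp0 <- fit_kplus_high(highseed[[1]], ctrl_par)
    ctrl_par <- update_params(ctrl_par, k_plus = kp0)
  }
  ctrl_fit <- global_fit(lowseed[[1]], ctrl_par, free = low_free,
                         n_starts = n_starts, seed = seed)
  if (!ctrl_fit$converged) stop("control fit failed")
  if (use_highseed) {
    # second pass: k_plus was pinned before k_2 was known
    kp0 <- fit_kplus_high(highseed[[1]], ctrl_fit$params)
    ctrl_fit <- global_fit(lowseed[[1]],
                           update_params(ctrl_fit$params, k_plus = kp0),
                           free = low_free, n_starts = 1, seed = seed)
    ctrl_fit$params <- update_params(ctrl_fit$params, k_plus = kp0)
  }
  ctrl_k2 <- ctrl_fit$params$k_2
  ctrl_kp <- ctrl_fit$params$k_plus

  # --- per-dose refits ---
  # sequential attribution, alternated until each constant is stable when
  # refitted with the other at its dose-specific (not control) value
  k2 <- kp <- numeric(length(doses))
  k2[1] <- ctrl_k2; kp[1] <- ctrl_kp
  for (i in seq_along(doses)[-1]) {
    par_i <- ctrl_fit$params
    prev <- c(NA_real_, NA_real_)
    for (pass in 1:4) {
      if (length(low_free)) {
        fit_i <- global_fit(lowseed[[i]], par_i, free = low_free,
                            n_starts = 1, seed = seed)
        k2[i] <- fit_i$params$k_2
        par_i <- update_params(par_i, k_2 = k2[i])
        if (!use_highseed && "k_plus" %in% free) {
          kp[i] <- fit_i$params$k_plus
          par_i <- update_params(par_i, k_plus = kp[i])
        }
      } else k2[i] <- ctrl_k2
      if (use_highseed) {
        kp[i] <- fit_kplus_high(highseed[[i]], par_i)
        par_i <- update_params(par_i, k_plus = kp[i])
      } else if (!("k_plus" %in% free)) kp[i] <- ctrl_kp
      if (!use_highseed && !length(low_free)) break
      cur <- c(k2[i], kp[i])
      if (!anyNA(prev) && all(abs(cur / prev - 1) < 0.005)) break
      prev <- cur
    }
  }

  slopes <- NULL
  if (!is.null(highseed)) {
    slopes <- vapply(highseed, function(trs) {
      mean(vapply(trs, function(tr) elongation_slope(tr), numeric(1)))
    }, numeric(1))
  }

  top <- length(doses)
  structure(list(
    compound_id = series$compound_id,
    doses = doses,
    constants = data.frame(dose = doses, k_2 = k2, k_plus = kp),
    delta_k2 = if ("k_2" %in% free) 1 - k2[top] / k2[1] else NA_real_,
    delta_kplus = if ("k_plus" %in% free) 1 - kp[top] / kp[1] else NA_real_,
    elongation_slopes = slopes,
    control_fit = ctrl_fit), class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("<mechanism_report> %s: at top dose k2 reduced %.1f%%, k+ reduced %.1f%%\n",
              x$compound_id, 100 * x$delta_k2, 100 * x$delta_kplus))
  invisible(x)
}

#' Early-time elongation slope of a high-seed trace
#'
#' Ordinary least-squares slope of the signal over the first `window`
#' hours, the standard readout of seeded elongation assays where early
#' growth is linear in time. The ratio of compound to control slopes
#' quantifies elongation inhibition.
#'
#' @param trace A [kinetic_trace()].
#' @param window Window length in hours (default 10).
#' @param se Return `c(slope, se)` instead of the slope alone.
#' @return Slope in signal units per second.
#' @export
elongation_slope <- function(trace, window = 10, se = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  wsec <- window * 3600
  if (max(trace$time) < wsec) stop("window exceeds trace span")
  keep <- trace$time <= wsec
  fit <- stats::lm(trace$signal[keep] ~ trace$time[keep])
  if (!se) return(unname(stats::coef(fit)[2]))
  sm <- suppressWarnings(summary(fit)$coefficients)
  c(slope = sm[2, 1], se = sm[2, 2])
}

#' Kinetic inhibitory concentration (KIC50)
#'
#' The compound concentration that halves the approximate aggregation
#' rate 1/t1/2, normalized so the vehicle control is 100 and complete
#' arrest is 0. A descending log-dose logistic with top fixed at 100 and
#' bottom fixed at 0 (Hill slope free) is fitted and the KIC50 is the
#' dose at which the curve crosses 50.
#'
#' @param doses Compound doses in molar (excluding the control).
#' @param half_times Half-times (seconds) at those doses.
#' @param control_half_time Vehicle-control half-time (seconds).
#' @return List with `kic50` (molar), `se`, `hill`, `rates`
#'   (the normalized rates) and `flag` ("ok", "weak_inhibition" when no
#'   dose brings the rate below 75 so only the bound "> max dose" is
#'   reported, or "non_monotone").
#' @export
kic50 <- function(doses, half_times, control_half_time) {
  if (length(doses) != length(half_times)) stop("length mismatch")
  if (length(doses) < 4) stop("need >= 4 doses spanning the transition")
  if (any(doses <= 0)) stop("doses must be positive (control passed separately)")
  rates <- (control_half_time / half_times) * 100  # vehicle = 100
  if (min(rates) > 75) {
    return(list(kic50 = NA_real_, se = NA_real_, hill = NA_real_,
                rates = rates, flag = "weak_inhibition",
                bound = paste0("> ", max(doses))))
  }
  flag <- "ok"
  ord <- order(doses)
  if (any(diff(rates[ord]) > 15)) flag <- "non_monotone"
  dat <- data.frame(ld = log10(doses), r = rates)
  ic0 <- 10^stats::approx(rates[ord], log10(doses[ord]), xout = 50,
                          ties = mean, rule = 2)$y
  fit <- minpack.lm::nlsLM(
    r ~ 100 / (1 + 10^(h * (ld - log10(ic)))),
    data = dat, start = list(ic = ic0, h = 1),
    lower = c(min(doses) / 100, 0.1), upper = c(max(doses) * 100, 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["ic"]],
                 error = function(e) NA_real_)
  list(kic50 = unname(cf[["ic"]]), se = se, hill = unname(cf[["h"]]),
       rates = rates, flag = flag)
}
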