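#' Linear-trapezoidal AUC over an interval
#'
#' Area under the concentration-time curve by the linear trapezoidal rule,
#' clipped to `[t_start, t_end]`. Boundary concentrations not on the sampling
#' grid are obtained by linear interpolation between the bracketing samples;
#' no extrapolation beyond the sampled range is performed.
#'
#' @param profile A [conc_profile()] with no BLQ records, or a data.frame
#'   with columns `time` and `conc`.
#' @param t_start,t_end Interval bounds in hours, `t_start < t_end`.
#' @return AUC in ng*h/mL (or ng*h/g for solid tissues).
#' @export
auc_trapezoid <- function(profile, t_start, t_end) {
  d <- nca_data(profile)
  if (t_start >= t_end) stop("'t_start' must be < 't_end'")
  if (t_start < min(d$time) || t_end > max(d$time)) {
    stop(sprintf(paste0("interval [%g, %g] extends beyond the sampled range ",
                        "[%g, %g]; no extrapolation in partial AUC"),
                 t_start, t_end, min(d$time), max(d$time)))
  }
  tt <- sort(unique(c(d$time, t_start, t_end)))
  tt <- tt[tt >= t_start & tt <= t_end]
  cc <- stats::approx(d$time, d$conc, xout = tt, ties = "ordered")$y
  sum(diff(tt) * (utils::head(cc, -1) + utils::tail(cc, -1)) / 2)
}

# Extract a clean numeric (time, conc) table for NCA; BLQ must be resolved.
nca_data <- function(profile) {
  if (inherits(profile, "conc_profile")) {
    if (any(profile$data$blq)) {
      stop("profile still contains BLQ records; apply censor_blq() first")
    }
    d <- profile$data[c("time", "conc")]
  } else if (is.data.frame(profile)) {
    stopifnot(all(c("time", "conc") %in% names(profile)))
    d <- profile[c("time", "conc")]
  } else {
    stop("'profile' must be a conc_profile or a data.frame(time, conc)")
  }
  if (anyNA(d$conc)) stop("missing concentrations in profile")
  d
}

#' Maximum observed concentration and its time
#'
#' @param profile A [conc_profile()] or data.frame with `time`, `conc`.
#'   BLQ records are ignored.
#' @return List with `c_max` and `t_max`; ties broken to the earliest time.
#' @export
cmax_tmax <- function(profile) {
  d <- if (inherits(profile, "conc_profile")) {
    profile$data[!profile$data$blq, c("time", "conc")]
  } else {
    profile[c("time", "conc")]
  }
  d <- d[!is.na(d$conc), , drop = FALSE]
  if (nrow(d) == 0L) stop("no quantifiable records")
  i <- which.max(d$conc)   # which.max returns the first maximum
  list(c_max = d$conc[i], t_max = d$time[i])
}

#' Terminal rate constant by log-linear regression
#'
#' Ordinary least squares on (t, ln C) over a terminal window of at least
#' `min_points` samples. The default `"best_fit"` selection scans every
#' suffix window of the positive-concentration samples after Tmax (the Cmax
#' sample itself is excluded), keeps the window with the largest adjusted
#' R-squared, and breaks near-ties (within `tie_tol`) toward the window with
#' more points. `"manual"` uses the caller-supplied time window.
#'
#' @param profile A [conc_profile()] (BLQ-censored) or data.frame.
#' @param selection `"best_fit"` (default) or `"manual"`.
#' @param min_points Minimum number of regression points (default 3).
#' @param window For `selection = "manual"`: numeric length-2 time window
#'   (inclusive) over which to regress.
#' @param tie_tol Adjusted-R-squared tolerance within which a larger window
#'   is preferred (default 1e-4).
#' @return List with `lambda_z` (1/h, `NA` if not estimable), `points_used`,
#'   `r2_adj`, `window` (time range used) and `estimable`.
#' @export
estimate_lambda_z <- function(profile, selection = c("best_fit", "manual"),
                              min_points = 3L, window = NULL,
                              tie_tol = 1e-4) {
  selection <- match.arg(selection)
  d <- nca_data(profile)
  d <- d[d$conc > 0, , drop = FALSE]
  if (selection == "manual") {
    if (is.null(window) || length(window) != 2L) {
      stop("manual selection requires a length-2 'window'")
    }
    pts <- d[d$time >= window[1] & d$time <= window[2], , drop = FALSE]
    if (nrow(pts) < min_points) {
      stop("insufficient data: fewer than ", min_points,
           " positive concentrations in the requested window")
    }
    return(lambda_fit(pts))
  }
  i_max <- which.max(d$conc)
  cand <- d[seq_len(nrow(d)) > i_max, , drop = FALSE]  # strictly post-Tmax
  n <- nrow(cand)
  if (n < min_points) {
    stop("insufficient data: fewer than ", min_points,
         " positive concentrations after Tmax")
  }
  best <- NULL
  for (k in seq(min_points, n)) {          # suffix windows, small to large
    fit <- lambda_fit(cand[seq(n - k + 1L, n), , drop = FALSE])
    if (!fit$estimable) next
    if (is.null(best) || fit$r2_adj > best$r2_adj + tie_tol ||
        (fit$r2_adj >= best$r2_adj - tie_tol &&
         fit$points_used > best$points_used)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    return(list(lambda_z = NA_real_, points_used = 0L, r2_adj = NA_real_,
                window = c(NA_real_, NA_real_), estimable = FALSE))
  }
  best
}

lambda_fit <- function(pts) {
  x <- pts$time
  y <- log(pts$conc)
  n <- length(x)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- fit$coefficients[2]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  r2_adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
  lam <- -unname(slope)
  list(lambda_z = if (lam > 0) lam else NA_real_, points_used = n,
       r2_adj = r2_adj, window = range(x), estimable = lam > 0)
}

#' Apparent terminal half-life
#'
#' `0.693 / lambda_z`, using the conventional rounded constant 0.693 rather
#' than `log(2)` (the difference is below 0.03 percent).
#'
#' @param lambda_z Terminal rate constant in 1/h; must be positive.
#' @return Half-life in hours.
#' @export
half_life <- function(lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("'lambda_z' must be positive")
  }
  0.693 / lambda_z
}

#' Extrapolate AUC to infinity
#'
#' `AUC(0-inf) = AUC(0-tlast) + Clast / lambda_z`, with the extrapolated
#' fraction reported for quality control.
#'
#' @param auc_0_t AUC to the last measurable concentration.
#' @param c_last Last measurable concentration (>= 0).
#' @param lambda_z Terminal rate constant (> 0).
#' @return List with `auc_0_inf` and `extrapolated_fraction`.
#' @export
auc_to_infinity <- function(auc_0_t, c_last, lambda_z) {
  if (!is.finite(lambda_z) || lambda_z <= 0) stop("'lambda_z' must be positive")
  if (c_last < 0) stop("'c_last' must be >= 0")
  tail <- c_last / lambda_z
  auc_inf <- auc_0_t + tail
  list(auc_0_inf = auc_inf,
       extrapolated_fraction = if (auc_inf > 0) tail / auc_inf else 0)
}

#' Plasma clearance after IV bolus dosing
#'
#' `CL = dose / AUC(0-inf)` with units handled so the result is in
#' mL/min/kg: dose in mg/kg is 1e6 ng/kg, divided by AUC in ng*h/mL gives
#' mL/h/kg, divided by 60 gives mL/min/kg.
#'
#' @param dose Dose in mg/kg.
#' @param auc_0_inf AUC extrapolated to infinity, ng*h/mL.
#' @param route Administration route; must be `"IV"`.
#' @return Clearance in mL/min/kg.
#' @export
clearance_iv <- function(dose, auc_0_inf, route = "IV") {
  if (!identical(route, "IV")) {
    stop("plasma clearance is defined here for IV dosing only")
  }
  if (auc_0_inf <= 0) stop("'auc_0_inf' must be positive")
  (dose * 1e6 / auc_0_inf) / 60
}

#' Steady-state volume of distribution after IV bolus
#'
#' `Vdss = CL * MRT` with `MRT = AUMC(0-inf) / AUC(0-inf)`. AUMC is the
#' linear-trapezoidal area under t*C(t) plus the analytic tail
#' `Clast * (tlast/lambda + 1/lambda^2)`.
#'
#' @param dose Dose in mg/kg.
#' @param profile BLQ-censored [conc_profile()] or data.frame, starting at
#'   `t = 0` (use [run_nca()] for automatic C(0) handling).
#' @param lambda_z Terminal rate constant (1/h).
#' @return Vdss in L/kg (`NA` if `lambda_z` is not estimable).
#' @export
vdss_iv <- function(dose, profile, lambda_z) {
  d <- nca_data(profile)
  if (!is.finite(lambda_z) || lambda_z <= 0) return(NA_real_)
  t_last <- max(d$time)
  c_last <- d$conc[which.max(d$time)]
  auc <- auc_to_infinity(auc_trapezoid(d, min(d$time), t_last), c_last,
                         lambda_z)$auc_0_inf
  dm <- data.frame(time = d$time, conc = d$time * d$conc)
  aumc <- auc_trapezoid(dm, min(d$time), t_last) +
    c_last * (t_last / lambda_z + 1 / lambda_z^2)
  mrt <- aumc / auc                         # hours
  cl <- clearance_iv(dose, auc)             # mL/min/kg
  cl * 60 * mrt / 1000                      # -> L/kg
}

#' Oral bioavailability from dose-normalized AUC
#'
#' `F = (AUC_PO / dose_PO) / (AUC_IV / dose_IV)`. Values above 1 are
#' reported as-is with `above_unity = TRUE`.
#'
#' @param auc_po,dose_po Oral AUC(0-inf) and dose.
#' @param auc_iv,dose_iv IV AUC(0-inf) and dose.
#' @return List with `f` (fraction) and `above_unity` flag.
#' @export
bioavailability <- function(auc_po, dose_po, auc_iv, dose_iv) {
  if (auc_iv <= 0 || dose_iv <= 0 || dose_po <= 0) {
    stop("doses and IV AUC must be positive")
  }
  f <- (auc_po / dose_po) / (auc_iv / dose_iv)
  list(f = f, above_unity = f > 1)
}

#' Cross-profile exposure ratio
#'
#' The generic numerator/denominator comparison behind tissue/plasma
#' partitioning ratios and multiple-dose:single-dose accumulation ratios.
#'
#' @param numerator,denominator Metric values (e.g. AUC(0-24h) of tissue and
#'   plasma); denominator must be positive.
#' @param kind One of `"tissue_plasma"`, `"accumulation"`, `"generic"`;
#'   controls the display rounding in [format_ratio()].
#' @return List with `value` (raw ratio) and `display` (string rounded to
#'   the reporting precision: nearest integer for tissue/plasma, one decimal
#'   for accumulation).
#' @export
exposure_ratio <- function(numerator, denominator,
                           kind = c("tissue_plasma", "accumulation",
                                    "generic")) {
  kind <- match.arg(kind)
  if (is.na(numerator) || is.na(denominator)) {
    stop("metric missing on one side of the ratio")
  }
  if (denominator <= 0) stop("denominator must be positive")
  v <- numerator / denominator
  list(value = v, display = format_ratio(v, kind))
}

#' Format a ratio at reporting precision
#'
#' Tissue/plasma ratios are reported to the nearest integer, accumulation
#' ratios to one decimal; half-way cases round away from zero.
#'
#' @param value Ratio value.
#' @param kind See [exposure_ratio()].
#' @return Character scalar.
#' @export
format_ratio <- function(value, kind = c("tissue_plasma", "accumulation",
                                         "generic")) {
  kind <- match.arg(kind)
  digits <- switch(kind, tissue_plasma = 0L, accumulation = 1L, generic = 2L)
  sprintf(paste0("%.", digits, "f"), round_half_up(value, digits))
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Dose-proportionality regression
#'
#' Ordinary least-squares line of an exposure metric (AUC or Cmax) against
#' dose, with R-squared, to assess linear kinetics across dose levels.
#'
#' @param dose Numeric vector of doses (mg/kg); at least 2 distinct values.
#' @param metric Numeric vector of metric values, same length.
#' @return List with `slope`, `intercept`, `r_squared`, `n` and `degenerate`
#'   (`TRUE` when only two points, where R-squared is 1 by construction).
#' @export
dose_proportionality <- function(dose, metric) {
  stopifnot(length(dose) == length(metric), length(dose) >= 2L)
  if (length(unique(dose)) < 2L) stop("need at least 2 distinct doses")
  fit <- stats::lm(metric ~ dose)
  ss_tot <- sum((metric - mean(metric))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = length(dose), degenerate = length(dose) == 2L)
}
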