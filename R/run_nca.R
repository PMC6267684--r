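#' Full non-compartmental analysis of one profile
#'
#' Composes the NCA primitives into the complete parameter set for one
#' (arm, matrix) profile, following standard extravascular / IV-bolus
#' conventions:
#'
#' * BLQ records are resolved by [censor_blq()] with the given policy.
#' * IV bolus: if no `t = 0` sample exists, C(0) is back-extrapolated
#'   log-linearly from the first two positive concentrations (falling back to
#'   the first observed concentration if the initial phase is not declining).
#' * Extravascular: C(0) = 0 is inserted when absent.
#' * Partial AUCs (0-24 h, 0-48 h) use linear interpolation at interval
#'   boundaries and are `NA` when the profile does not reach the bound.
#' * lambda-z by the best-fit terminal window ([estimate_lambda_z()]);
#'   when not estimable the extrapolation-dependent parameters are `NA`.
#' * Quasi-continuous (chow) regimens are treated as a steady-state
#'   observation window: only AUC(0-24h), Cmax/Tmax and Cmean are computed,
#'   and no terminal phase is attempted.
#'
#' @param profile A [conc_profile()].
#' @param blq_policy Passed to [censor_blq()].
#' @param lambda_selection,lambda_window Passed to [estimate_lambda_z()].
#' @return An object of class `nca_result`: a list of PK parameters
#'   (`auc_0_t`, `auc_0_24`, `auc_0_48`, `auc_0_inf`, `lambda_z`,
#'   `lambda_points`, `lambda_r2_adj`, `t_half`, `c_max`, `t_max`, `c_last`,
#'   `t_last`, `cl_p`, `vd_ss`, `c_mean`, `extrapolated_fraction`) plus
#'   bookkeeping (`arm_id`, `matrix`, `route`, `dose`, `unit`, `c0`,
#'   `flags`).
#' @export
run_nca <- function(profile, blq_policy = "pre_tmax_zero_post_tmax_drop",
                    lambda_selection = "best_fit", lambda_window = NULL) {
  stopifnot(inherits(profile, "conc_profile"))
  if (any(profile$data$blq)) profile <- censor_blq(profile, blq_policy)
  route <- profile$regimen$route
  dose <- profile$regimen$dose_level
  d <- profile$data[c("time", "conc")]
  flags <- character()

  obs <- cmax_tmax(d)
  chow <- route == "PO_chow"

  # origin handling
  c0 <- NA_real_
  if (!any(d$time == 0)) {
    if (route == "IV") {
      pos <- d[d$conc > 0, , drop = FALSE]
      if (nrow(pos) >= 2 && pos$conc[2] < pos$conc[1]) {
        sl <- (log(pos$conc[2]) - log(pos$conc[1])) /
          (pos$time[2] - pos$time[1])
        c0 <- exp(log(pos$conc[1]) - sl * pos$time[1])
      } else {
        c0 <- d$conc[1]
        flags <- c(flags, "c0_carried_back")
      }
      d <- rbind(data.frame(time = 0, conc = c0), d)
    } else if (!chow) {
      d <- rbind(data.frame(time = 0, conc = 0), d)
    }
  }

  t_last <- max(d$time[d$conc > 0])
  c_last <- d$conc[d$time == t_last]
  auc_0_t <- auc_trapezoid(d, min(d$time), t_last)
  span <- max(d$time)
  auc_0_24 <- if (span >= 24) auc_trapezoid(d, min(d$time), 24) else NA_real_
  auc_0_48 <- if (span >= 48) auc_trapezoid(d, min(d$time), 48) else NA_real_

  lam <- list(lambda_z = NA_real_, points_used = NA_integer_,
              r2_adj = NA_real_, estimable = FALSE)
  if (!chow) {
    lam <- tryCatch(
      estimate_lambda_z(d, selection = lambda_selection,
                        window = lambda_window),
      error = function(e) {
        flags <<- c(flags, paste0("lambda: ", conditionMessage(e)))
        list(lambda_z = NA_real_, points_used = NA_integer_,
             r2_adj = NA_real_, estimable = FALSE)
      })
    if (!lam$estimable) flags <- c(flags, "lambda_not_estimable")
  }

  if (lam$estimable) {
    ext <- auc_to_infinity(auc_0_t, c_last, lam$lambda_z)
    auc_inf <- ext$auc_0_inf
    ext_frac <- ext$extrapolated_fraction
    t_half <- half_life(lam$lambda_z)
  } else {
    auc_inf <- NA_real_; ext_frac <- NA_real_; t_half <- NA_real_
  }

  cl_p <- vd <- NA_real_
  if (route == "IV" && profile$matrix == "plasma" && lam$estimable) {
    cl_p <- clearance_iv(dose, auc_inf)
    vd <- vdss_iv(dose, d, lam$lambda_z)
  }

  structure(list(
    arm_id = profile$arm_id, matrix = profile$matrix, route = route,
    dose = dose, unit = profile$unit,
    auc_0_t = auc_0_t, auc_0_24 = auc_0_24, auc_0_48 = auc_0_48,
    auc_0_inf = auc_inf,
    lambda_z = lam$lambda_z, lambda_points = lam$points_used,
    lambda_r2_adj = lam$r2_adj, t_half = t_half,
    c_max = obs$c_max, t_max = obs$t_max, c0 = c0,
    c_last = c_last, t_last = t_last,
    cl_p = cl_p, vd_ss = vd,
    c_mean = if (!is.na(auc_0_24)) auc_0_24 / 24 else NA_real_,
    extrapolated_fraction = ext_frac,
    flags = flags), class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> arm '%s', %s, %s %g mg/kg\n", x$arm_id,
              x$matrix, x$route, x$dose))
  num <- c("auc_0_24", "auc_0_48", "auc_0_inf", "lambda_z", "t_half",
           "c_max", "t_max", "cl_p", "vd_ss", "c_mean",
           "extrapolated_fraction")
  for (p in num) {
    cat(sprintf("  %-22s %s\n", p,
                if (is.na(x[[p]])) "NA" else format(signif(x[[p]], 4))))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Collect NCA results into a parameter table
#'
#' @param results List of [run_nca()] results.
#' @return A data.frame, one row per profile.
#' @export
nca_table <- function(results) {
  cols <- c("arm_id", "matrix", "route", "dose", "auc_0_t", "auc_0_24",
            "auc_0_48", "auc_0_inf", "lambda_z", "lambda_points",
            "lambda_r2_adj", "t_half", "c_max", "t_max", "c_last", "t_last",
            "cl_p", "vd_ss", "c_mean", "extrapolated_fraction")
  do.call(rbind, lapply(results, function(r) {
    v <- lapply(cols, function(cc) if (is.null(r[[cc]])) NA else r[[cc]])
    names(v) <- cols
    as.data.frame(v, stringsAsFactors = FALSE)
  }))
}
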