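#' Marker-selection criteria
#'
#' Thresholds of the expression-normalization filter that picks transcripts
#' whose dysregulation in tumor is reverted toward the normal-tissue level
#' by treatment while staying stable in treated normal tissue. The four
#' contrasts are: tm/tv (treated vs vehicle tumor), pm/pv (treated vs
#' vehicle normal pancreas) and pv/tv (vehicle pancreas vs vehicle tumor).
#'
#' @param min_abs_fc_tm_tv Minimum |fold change| tumor treated vs tumor
#'   vehicle (default 3; inclusive).
#' @param max_abs_fc_pm_pv Maximum |fold change| pancreas treated vs
#'   pancreas vehicle (default 2; exclusive — the gene must stay below it).
#' @param min_product Minimum of `fc_tm_tv * fc_pv_tv` (default 9;
#'   exclusive). Under the signed convention the product is positive only
#'   when the treatment effect moves expression in the same direction as
#'   the normal-vs-tumor difference, i.e. toward normalization.
#' @param max_p_value Per-gene p-value cutoff (default 0.001; exclusive).
#' @return An object of class `marker_criteria`.
#' @export
marker_criteria <- function(min_abs_fc_tm_tv = 3, max_abs_fc_pm_pv = 2,
                            min_product = 9, max_p_value = 0.001) {
  vals <- c(min_abs_fc_tm_tv, max_abs_fc_pm_pv, min_product, max_p_value)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all thresholds must be positive")
  }
  structure(list(min_abs_fc_tm_tv = min_abs_fc_tm_tv,
                 max_abs_fc_pm_pv = max_abs_fc_pm_pv,
                 min_product = min_product,
                 max_p_value = max_p_value),
            class = "marker_criteria")
}

#' Select normalization-marker transcripts
#'
#' Applies the four-way filter to a table of per-gene signed fold changes.
#' Fold changes must use the signed convention: a down-regulation of
#' magnitude x is encoded as -x (never as 1/x), so no |fold change| below 1
#' can occur. A gene is selected iff
#' `|fc_tm_tv| >= min_abs_fc_tm_tv` and `|fc_pm_pv| < max_abs_fc_pm_pv` and
#' `fc_tm_tv * fc_pv_tv > min_product` and `p_value < max_p_value`.
#' Output preserves input order; the filter is deterministic.
#'
#' @param records Data.frame with columns `gene_id`, `fc_tm_tv`,
#'   `fc_pm_pv`, `fc_pv_tv`, `p_value`.
#' @param criteria A [marker_criteria()].
#' @return Character vector of selected `gene_id`s.
#' @export
select_markers <- function(records, criteria = marker_criteria()) {
  stopifnot(is.data.frame(records), inherits(criteria, "marker_criteria"))
  need <- c("gene_id", "fc_tm_tv", "fc_pm_pv", "fc_pv_tv", "p_value")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("fold-change table lacks column(s): ",
                         paste(miss, collapse = ", "))
  fc <- as.matrix(records[c("fc_tm_tv", "fc_pm_pv", "fc_pv_tv")])
  if (any(abs(fc) < 1)) {
    stop("fold changes in (-1, 1) detected: input appears to use the ratio ",
         "convention; encode down-regulation of magnitude x as -x")
  }
  p <- records$p_value
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pass <- abs(records$fc_tm_tv) >= criteria$min_abs_fc_tm_tv &
    abs(records$fc_pm_pv) < criteria$max_abs_fc_pm_pv &
    records$fc_tm_tv * records$fc_pv_tv > criteria$min_product &
    p < criteria$max_p_value
  as.character(records$gene_id[pass])
}

#' Read a fold-change table
#'
#' @param source CSV path with columns `gene_id, fc_tm_tv, fc_pm_pv,
#'   fc_pv_tv, p_value`.
#' @return Data.frame suitable for [select_markers()].
#' @export
read_fold_changes <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("gene_id", "fc_tm_tv", "fc_pm_pv", "fc_pv_tv", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fold-change table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' PNC prevalence of a treatment group
#'
#' Per-sample prevalence is the fraction of scored cells containing at least
#' one perinucleolar compartment (PNC); the group value is the unweighted
#' mean across samples.
#'
#' @param counts Data.frame with columns `sample_id`, `group`,
#'   `cells_total`, `cells_with_pnc`.
#' @param group Group to summarize (e.g. `"vehicle"` or `"treated"`).
#' @return Group mean prevalence in `[0, 1]`.
#' @export
pnc_prevalence <- function(counts, group) {
  pv <- pnc_sample_prevalence(counts, group)
  mean(pv)
}

pnc_sample_prevalence <- function(counts, group) {
  stopifnot(is.data.frame(counts),
            all(c("group", "cells_total", "cells_with_pnc") %in%
                  names(counts)))
  g <- counts[counts$group == group, , drop = FALSE]
  if (nrow(g) == 0L) stop("no samples in group '", group, "'")
  if (any(g$cells_total <= 0)) stop("'cells_total' must be positive")
  if (any(g$cells_with_pnc < 0 | g$cells_with_pnc > g$cells_total)) {
    stop("'cells_with_pnc' must lie in [0, cells_total]")
  }
  g$cells_with_pnc / g$cells_total
}

#' Compare PNC prevalence between two groups
#'
#' Two-sample two-tailed t-test on the per-sample prevalences (equal
#' variance by default, Welch optionally), as used for vehicle-vs-treated
#' tumor comparisons with a handful of tumors per arm.
#'
#' @param counts Data.frame as in [pnc_prevalence()].
#' @param vehicle,treated Group labels.
#' @param var_equal Pooled-variance t-test when `TRUE` (default).
#' @return List with `difference` (treated - vehicle mean prevalence),
#'   `p_value`, and the per-group means.
#' @export
compare_prevalence <- function(counts, vehicle = "vehicle",
                               treated = "treated", var_equal = TRUE) {
  pv <- pnc_sample_prevalence(counts, vehicle)
  pt_ <- pnc_sample_prevalence(counts, treated)
  if (length(pv) < 2L || length(pt_) < 2L) {
    stop("need at least 2 samples per group")
  }
  if (stats::var(pv) == 0 && stats::var(pt_) == 0) {
    return(list(difference = mean(pt_) - mean(pv),
                p_value = if (mean(pt_) == mean(pv)) 1 else 0,
                mean_vehicle = mean(pv), mean_treated = mean(pt_)))
  }
  tt <- stats::t.test(pt_, pv, var.equal = var_equal,
                      alternative = "two.sided")
  list(difference = mean(pt_) - mean(pv), p_value = tt$p.value,
       mean_vehicle = mean(pv), mean_treated = mean(pt_))
}

#' Exposure-response regression
#'
#' Least-squares fit of a relative expression level on tumor exposure
#' (AUC over 0-24 h) across dosing cohorts, with R-squared and its
#' two-tailed significance from the regression F/t test.
#'
#' @param auc Numeric vector of cohort exposures (ng*h/mL); at least 3
#'   points with non-constant exposure.
#' @param expression Numeric vector of relative expression values
#'   (reference-gene normalized), same length.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
exposure_response <- function(auc, expression) {
  stopifnot(length(auc) == length(expression))
  if (length(auc) < 3L) stop("need at least 3 cohorts")
  if (length(unique(auc)) < 2L) stop("exposure is constant across cohorts")
  fit <- stats::lm(expression ~ auc)
  n <- length(auc)
  ss_tot <- sum((expression - mean(expression))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  p <- if (r2 >= 1 - 1e-12) 0 else {
    fstat <- (r2 / (1 - r2)) * (n - 2)
    stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, p_value = p, n = n)
}
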