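#' Read a study configuration
#'
#' YAML description of a study: the analyte (molecular weight, per-matrix
#' LLOQs), the dosing arms, and the comparisons to derive (tissue/plasma
#' ratios, multiple:single-dose accumulation, bioavailability pairs,
#' dose-proportionality sets).
#'
#' @param path YAML file path.
#' @return List with `analyte` (an [analyte_spec()]), `arms`,
#'   `comparisons`.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analyte)) stop("config lacks an 'analyte' block")
  an <- analyte_spec(cfg$analyte$name, cfg$analyte$molecular_weight,
                     unlist(cfg$analyte$lloq))
  list(analyte = an, arms = cfg$arms, comparisons = cfg$comparisons)
}

#' Build minimal NCA results from a parameter table
#'
#' Wraps rows of an already-computed parameter table (for example a
#' published reference table, or the output of [nca_table()]) as
#' `nca_result` stubs so that [build_report()] comparisons can be computed
#' from stored parameters as well as from raw profiles.
#'
#' @param df Data.frame with at least `arm_id`, `matrix`, `route`, `dose`
#'   and any of the numeric NCA parameter columns.
#' @return Named list of `nca_result` objects (names `arm_id/matrix`).
#' @export
nca_results_from_params <- function(df) {
  stopifnot(all(c("arm_id", "matrix", "route", "dose") %in% names(df)))
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- as.list(df[i, , drop = FALSE])
    r <- lapply(r, function(v) if (is.factor(v)) as.character(v) else v)
    r$flags <- character()
    structure(r, class = "nca_result")
  })
  names(out) <- paste(df$arm_id, df$matrix, sep = "/")
  out
}

metric_of <- function(results, ref, metric) {
  r <- results[[ref]]
  if (is.null(r)) return(NULL)
  v <- r[[metric]]
  if (is.null(v) || length(v) != 1L || is.na(v)) return(NA_real_)
  v
}

#' Build the study report
#'
#' Produces the two study-level tables: a parameter table (one column per
#' arm/matrix, one row per NCA parameter) and a comparisons table resolving
#' every requested derived metric. Route-inapplicable cells (clearance and
#' Vdss outside IV dosing) are printed `NA`; parameters that could not be
#' calculated (terminal phase not estimable, interval not covered) are
#' printed `NC`. Unresolvable comparisons are listed with a reason and do
#' not stop the run. Output is deterministic in its inputs.
#'
#' @param results Named list of [run_nca()] results (names `arm/matrix`),
#'   or anything accepted by [nca_results_from_params()].
#' @param comparisons List of comparison requests, each a list with `kind`
#'   (`"tissue_plasma"`, `"accumulation"`, `"bioavailability"`,
#'   `"dose_proportionality"`) plus the references it needs (see the
#'   packaged `demo_study.yaml` for the schema).
#' @param sig_digits Significant digits for the parameter table (default 3).
#' @return Object of class `pk_report`: list with `parameters` (data.frame)
#'   and `comparisons` (data.frame).
#' @export
build_report <- function(results, comparisons = list(), sig_digits = 3L) {
  if (is.data.frame(results)) results <- nca_results_from_params(results)
  stopifnot(is.list(results), length(results) > 0)

  params <- c("dose", "route", "auc_0_24", "auc_0_48", "auc_0_inf",
              "t_half", "t_max", "c_max", "cl_p", "vd_ss", "c_mean")
  fmt_cell <- function(r, p) {
    v <- r[[p]]
    if (p == "route") return(as.character(v))
    if (p %in% c("cl_p", "vd_ss") && !identical(r$route, "IV")) return("NA")
    if (is.null(v) || length(v) != 1L || is.na(v)) return("NC")
    format(signif(v, sig_digits), big.mark = ",", scientific = FALSE)
  }
  tab <- vapply(results, function(r) vapply(params, fmt_cell, "", r = r),
                character(length(params)))
  parameters <- data.frame(parameter = params, tab, check.names = FALSE,
                           stringsAsFactors = FALSE)

  rows <- lapply(comparisons, function(cmp) resolve_comparison(results, cmp))
  comparisons_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), description = character(),
               value = numeric(), display = character(),
               note = character(), stringsAsFactors = FALSE)
  structure(list(parameters = parameters, comparisons = comparisons_df),
            class = "pk_report")
}

resolve_comparison <- function(results, cmp) {
  row <- function(desc, value, display, note = "") {
    data.frame(kind = cmp$kind, description = desc, value = value,
               display = display, note = note, stringsAsFactors = FALSE)
  }
  fail <- function(desc, why) row(desc, NA_real_, "NC", why)
  kind <- cmp$kind
  if (kind %in% c("tissue_plasma", "accumulation")) {
    metric <- if (is.null(cmp$metric)) "auc_0_24" else cmp$metric
    desc <- sprintf("%s %s / %s", metric, cmp$numerator, cmp$denominator)
    num <- metric_of(results, cmp$numerator, metric)
    den <- metric_of(results, cmp$denominator, metric)
    if (is.null(num) || is.null(den)) {
      return(fail(desc, "arm/matrix not found"))
    }
    if (is.na(num) || is.na(den) || den <= 0) {
      return(fail(desc, "metric missing"))
    }
    er <- exposure_ratio(num, den, kind = kind)
    return(row(desc, er$value, er$display))
  }
  if (kind == "bioavailability") {
    desc <- sprintf("F %s vs %s", cmp$po, cmp$iv)
    rp <- results[[cmp$po]]; ri <- results[[cmp$iv]]
    if (is.null(rp) || is.null(ri)) return(fail(desc, "arm not found"))
    ap <- metric_of(results, cmp$po, "auc_0_inf")
    ai <- metric_of(results, cmp$iv, "auc_0_inf")
    if (is.na(ap) || is.na(ai)) return(fail(desc, "AUC(0-inf) missing"))
    f <- bioavailability(ap, rp$dose, ai, ri$dose)
    return(row(desc, f$f, sprintf("%.0f%%", round_half_up(100 * f$f)),
               if (f$above_unity) "above unity" else ""))
  }
  if (kind == "dose_proportionality") {
    metric <- if (is.null(cmp$metric)) "auc_0_24" else cmp$metric
    desc <- sprintf("%s vs dose (%s)", metric,
                    paste(unlist(cmp$arms), collapse = ", "))
    vals <- vapply(unlist(cmp$arms), function(a) {
      v <- metric_of(results, a, metric)
      if (is.null(v)) NA_real_ else v
    }, numeric(1))
    doses <- vapply(unlist(cmp$arms), function(a) {
      r <- results[[a]]
      if (is.null(r)) NA_real_ else r$dose
    }, numeric(1))
    ok <- !is.na(vals) & !is.na(doses)
    if (sum(ok) < 2L) return(fail(desc, "fewer than 2 usable arms"))
    fit <- dose_proportionality(doses[ok], vals[ok])
    return(row(desc, fit$r_squared, sprintf("R2=%.3f", fit$r_squared),
               if (fit$degenerate) "2 points: R2=1 by construction" else ""))
  }
  fail(sprintf("(%s)", kind), "unknown comparison kind")
}

#' @export
print.pk_report <- function(x, ...) {
  cat("== PK parameters ==\n")
  print(x$parameters, row.names = FALSE)
  cat("\n== Comparisons ==\n")
  if (nrow(x$comparisons)) print(x$comparisons, row.names = FALSE)
  else cat("(none requested)\n")
  invisible(x)
}

#' Write a report to disk
#'
#' @param report A [build_report()] result.
#' @param out_dir Output directory (created if needed); writes
#'   `parameters.csv` and `comparisons.csv`.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pk_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$parameters,
                   file.path(out_dir, "parameters.csv"), row.names = FALSE)
  utils::write.csv(report$comparisons,
                   file.path(out_dir, "comparisons.csv"), row.names = FALSE)
  invisible(out_dir)
}
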