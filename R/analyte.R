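#' Analyte specification
#'
#' Bundles the physico-chemical and bioanalytical constants needed downstream:
#' the molecular weight (for molar conversion) and the per-matrix lower limit
#' of quantitation (LLOQ) of the assay.
#'
#' @param name Analyte name.
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @param lloq Named numeric vector of LLOQs, one entry per matrix
#'   (ng/mL for fluid matrices, ng/g for solid tissues). All values must be
#'   positive.
#' @return An object of class `analyte_spec`.
#' @examples
#' analyte_spec("metarrestin", 474.6, c(plasma = 1.0, liver = 5.0))
#' @export
analyte_spec <- function(name, molecular_weight, lloq = numeric()) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("'molecular_weight' must be a single positive number (g/mol)")
  }
  lloq <- unlist(lloq)
  if (length(lloq) > 0) {
    if (is.null(names(lloq)) || any(!nzchar(names(lloq)))) {
      stop("'lloq' must be a named vector (matrix -> concentration)")
    }
    if (any(!is.finite(lloq)) || any(lloq <= 0)) {
      stop("every LLOQ must be a positive finite number")
    }
  }
  structure(list(name = name, molecular_weight = molecular_weight,
                 lloq = lloq),
            class = "analyte_spec")
}

#' Default analyte: metarrestin
#'
#' Metarrestin (ML-246), MW 474.6 g/mol, with validated LLOQs of 1.0 ng/mL in
#' plasma and 5.0 ng/g in liver homogenate. Solid matrices without a validated
#' LLOQ (tumor, spleen) inherit the liver value, the assay being the same
#' tissue-homogenate method.
#'
#' @return An `analyte_spec`.
#' @export
metarrestin <- function() {
  analyte_spec("metarrestin", 474.6,
               c(plasma = 1.0, liver = 5.0, tumor = 5.0, spleen = 5.0))
}

#' @export
print.analyte_spec <- function(x, ...) {
  cat(sprintf("<analyte_spec> %s, MW %.1f g/mol\n", x$name,
              x$molecular_weight))
  if (length(x$lloq)) {
    cat("  LLOQ:", paste(sprintf("%s=%g", names(x$lloq), x$lloq),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dose regimen
#'
#' @param route One of `"IV"`, `"PO_gavage"`, `"PO_chow"`.
#' @param dose_level Dose in mg/kg. For chow, the nominal daily-equivalent
#'   dose (70 ppm chow corresponds to 10 mg/kg/day, 170 ppm to 25 mg/kg/day).
#' @param n_doses Number of administered doses (>= 1).
#' @param dose_interval Dosing interval in hours (ignored for single dose).
#' @return An object of class `dose_regimen`.
#' @export
dose_regimen <- function(route = c("IV", "PO_gavage", "PO_chow"),
                         dose_level, n_doses = 1L, dose_interval = 24) {
  route <- match.arg(route)
  if (!is.numeric(dose_level) || length(dose_level) != 1L || dose_level < 0) {
    stop("'dose_level' must be a single non-negative number (mg/kg)")
  }
  n_doses <- as.integer(n_doses)
  if (is.na(n_doses) || n_doses < 1L) stop("'n_doses' must be >= 1")
  if (dose_interval <= 0) stop("'dose_interval' must be positive (h)")
  structure(list(route = route, dose_level = dose_level, n_doses = n_doses,
                 dose_interval = dose_interval,
                 schedule = if (n_doses == 1L) "single"
                            else sprintf("daily x %d", n_doses)),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  cat(sprintf("<dose_regimen> %s %g mg/kg, %s\n", x$route, x$dose_level,
              x$schedule))
  invisible(x)
}

#' Convert a mass concentration to molar units
#'
#' ng/mL (fluids) or ng/g (solid tissues, taking tissue density as 1 g/mL)
#' divided by the molecular weight in g/mol gives micromolar directly:
#' 1 ng/mL = 1 ug/L, and ug/L / (g/mol) = umol/L.
#'
#' @param conc Concentration(s) in ng/mL or ng/g; non-negative.
#' @param analyte An [analyte_spec()].
#' @return Concentration(s) in uM.
#' @examples
#' to_molar(6200, metarrestin())   # 6.2 ug/g tissue -> ~13 uM
#' @export
to_molar <- function(conc, analyte) {
  stopifnot(inherits(analyte, "analyte_spec"))
  if (any(conc < 0, na.rm = TRUE)) stop("'conc' must be non-negative")
  conc / analyte$molecular_weight
}

#' Matrix unit convention
#'
#' Fluid matrices are reported in ng/mL, solid tissues in ng/g.
#' @param matrix Matrix name(s).
#' @return Character vector of units.
#' @export
matrix_unit <- function(matrix) {
  ifelse(matrix %in% c("plasma", "blood", "serum"), "ng/mL", "ng/g")
}
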