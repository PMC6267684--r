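Package: tumorpk
Title: Non-Compartmental Pharmacokinetics for Mouse Serial-Sacrifice
    Tumor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Non-compartmental analysis (NCA) of plasma and tissue
    concentration-time data from destructive-sampling (serial-sacrifice)
    mouse studies: linear-trapezoidal AUC with terminal-slope (lambda-z)
    extrapolation, half-life, clearance, steady-state volume of
    distribution, Cmax/Tmax, time-averaged concentration, and derived
    exposure comparisons (tissue/plasma partitioning, multiple-dose
    accumulation, oral bioavailability, dose proportionality, molar
    conversion). Includes a seeded compartmental simulator of
    serial-sacrifice study designs with tissue partitioning, log-normal
    assay error and LLOQ censoring, a fold-change-based pharmacodynamic
    marker-selection filter with PNC-prevalence group comparison and
    exposure-response regression, and study-level report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
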