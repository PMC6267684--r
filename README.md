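# tumorpk

Non-compartmental pharmacokinetics (NCA) and pharmacodynamic marker
selection for mouse **serial-sacrifice** studies — the destructive-sampling
designs in which every time point is the mean of a few euthanized animals
(typically n = 3), yielding one mean concentration–time curve per study arm
and matrix (plasma, tumor, spleen, liver).

The package targets preclinical programs of small molecules with strong
tissue partitioning, dosed IV, by oral gavage, or quasi-continuously via
medicated chow. It is aimed at DMPK scientists and modelers who need the
full study-level calculus, not just per-profile parameters.

## What it computes

**Per profile (NCA).** Linear-trapezoidal AUC (partial areas by boundary
interpolation, never extrapolated); terminal rate constant λz by log-linear
regression with a WinNonlin-style best-fit window search (≥ 3 points after
Tmax, max adjusted R², ties toward more points); t½ = 0.693/λz;
AUC₀₋∞ = AUC₀₋ₜ + C_last/λz with the extrapolated fraction as QC;
Cmax/Tmax (ties to earliest); for IV plasma, CLp = dose/AUC₀₋∞ and
Vd,ss = CL·MRT with AUMC tail correction and log-linear C(0)
back-extrapolation; Cmean = AUC₀₋₂₄ₕ/24 for steady-state windows. Assay
limits are respected: below-LLOQ samples are auto-flagged and censored
(pre-Tmax → 0, post-Tmax → dropped, by default).

**Across profiles.** Tissue/plasma AUC ratios, multiple-dose:single-dose
accumulation ratios, oral bioavailability F = (AUC_PO/D_PO)/(AUC_IV/D_IV),
molar conversion (ng/mL ÷ MW g/mol = µM; tissue at 1 g/mL), and
dose-proportionality regressions — assembled into report tables with the
field's `NC`/`NA` conventions.

**Synthetic studies.** A seeded 1-/2-compartment closed-form simulator of
the serial-sacrifice design: tissue partitioning (Kp, optionally a tissue
equilibration lag), repeated dosing and chow-as-mini-boluses, log-normal
assay error averaged over n animals per time point, and LLOQ censoring.
Presets (`preset_sim_spec()`) reproduce the reference program's arms.

**PD layer.** The expression-normalization marker filter on signed fold
changes — selected iff |FC_tm/tv| ≥ 3 ∧ |FC_pm/pv| < 2 ∧
FC_tm/tv·FC_pv/tv > 9 ∧ p < 0.001 — plus PNC-prevalence group comparison
(two-tailed t-test) and exposure–response regression.

See `vignettes/tumorpk-methods.Rmd` for the full methods account.

## Worked example

Simulate the 3 mg/kg IV serial-sacrifice arm and analyze it:

```r
library(tumorpk)
spec <- preset_sim_spec("iv_3", seed = 42)      # CL 48, Vss 17, CV 15%, n = 3
prof <- simulate_study(spec, matrices = "plasma")$plasma
run_nca(prof)
#> <nca_result> arm 'sim', plasma, IV 3 mg/kg
#>   auc_0_24               1125
#>   auc_0_inf              1179
#>   lambda_z               0.09161
#>   t_half                 7.565
#>   c_max                  553.7
#>   t_max                  0.1667
#>   cl_p                   42.42
#>   vd_ss                  11.39
#>   c_mean                 46.89
#>   extrapolated_fraction  0.04543
```

The estimated clearance (42.4 mL/min/kg) sits ~12 % below the simulator's
true 48 mL/min/kg: the sparse 7-point grid plus linear trapezoid slightly
overestimates AUC — the design's own bias, quantified by the package's
recovery experiment (median |error| ≈ 8 % over 200 replicate studies).

Derived study-level metrics from the packaged reference parameter table:

```r
rep_ <- build_report(reference_pk_parameters(),
                     read_study_config(demo_study_config())$comparisons)
rep_$comparisons[c(1, 6, 9, 13), c("description", "value", "display")]
#>                          description     value display
#>  auc_0_inf po_3/liver / po_3/plasma 78.760046      79
#> auc_0_24 md_25/tumor / md_25/plasma 36.507937      37
#>  auc_0_24 md_25/tumor / sd_25/tumor  4.956897     5.0
#>        F po_3/plasma vs iv_3/plasma  0.837500     84%
```

Read: liver exposure is ~79× plasma after a 3 mg/kg oral dose; day-14
tumor exposure is 37× plasma; tumor accumulates 5.0-fold under daily
dosing (vs 1.8 for liver — evidence of tumor-selective retention); oral
bioavailability is 84 %.

A thin CLI wraps the same functions:

```sh
exec/nca simulate --arm iv_3 --seed 1 --out profiles.csv
exec/nca run --input profiles.csv --out results.csv
exec/nca select-markers --input fold_changes.csv
exec/nca report --input profiles.csv --config inst/extdata/demo_study.yaml --out-dir results/
```

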