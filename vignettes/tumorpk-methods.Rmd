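---
title: "Methods: non-compartmental PK and PD marker selection for serial-sacrifice mouse studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-compartmental PK and PD marker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorpk)
```

## The problem

Preclinical mouse PK studies of small molecules with strong tissue
partitioning — here an anti-metastatic pyrrolo-pyrimidine dosed IV, by oral
gavage and by medicated chow — use *serial-sacrifice* (destructive) designs:
each time point is the mean of a few animals (typically n = 3) euthanized at
that time, so one obtains a single mean concentration–time curve per arm and
matrix (plasma, tumor, spleen, liver) rather than longitudinal individual
profiles. `tumorpk` implements the complete calculus applied to such data:
non-compartmental analysis (NCA) per profile, derived exposure comparisons
across profiles, a seeded simulator of the design for validation, and the
pharmacodynamic computations used downstream (a fold-change
"expression-normalization" marker filter, perinucleolar-compartment (PNC)
prevalence comparison, and exposure–response regression).

## Non-compartmental analysis

For a profile \(C(t)\) observed at times \(t_1 < \dots < t_n\):

* **AUC** by the linear trapezoidal rule,
  \(\mathrm{AUC} = \sum_i (t_{i+1}-t_i)(C_i + C_{i+1})/2\). Partial areas
  (0–24 h, 0–48 h) interpolate linearly at interval boundaries and are never
  extrapolated beyond \(t_{last}\); they are reported missing when the
  profile does not span the interval.
* **Terminal slope** \(\lambda_z\) by ordinary least squares on
  \((t, \ln C)\). The default window search is the WinNonlin-style
  "best fit": every suffix of the positive post-\(T_{max}\) samples with at
  least 3 points is fitted, the window with the largest adjusted \(R^2\)
  wins, and near-ties (within \(10^{-4}\)) go to the larger window. The
  \(C_{max}\) sample itself is excluded, since absorption or distribution
  still contaminates it. A non-negative slope means \(\lambda_z\) is not
  estimable; everything downstream of the extrapolation is then flagged
  missing rather than guessed.
* **Half-life** \(t_{1/2} = 0.693/\lambda_z\). The rounded constant 0.693
  is used deliberately (the convention of the originating analysis software)
  rather than \(\ln 2\); the difference is below 0.03 %.
* **Extrapolation** \(\mathrm{AUC}_{0-\infty} = \mathrm{AUC}_{0-t_{last}} +
  C_{last}/\lambda_z\), with the extrapolated fraction reported as a QC
  quantity.
* **IV bolus parameters**: plasma clearance
  \(CL_p = \mathrm{dose}/\mathrm{AUC}_{0-\infty}\) (mL/min/kg after unit
  conversion) and steady-state volume
  \(V_{d,ss} = CL \cdot \mathrm{MRT}\) with
  \(\mathrm{MRT} = \mathrm{AUMC}/\mathrm{AUC}\), the AUMC tail being
  \(C_{last}(t_{last}/\lambda_z + 1/\lambda_z^2)\). When the first sample
  is later than \(t=0\), \(C(0)\) is back-extrapolated log-linearly from
  the first two positive concentrations (carried back flat if the initial
  phase is not declining). For extravascular routes \(C(0)=0\).
* **Cmean** \(= \mathrm{AUC}_{0-24h}/24\), the time-averaged concentration
  used for steady-state (chow) exposure. Chow profiles are treated as a
  steady-state observation window: AUC\(_{0-24h}\), \(C_{max}\)/\(T_{max}\)
  and Cmean only, no terminal phase.

Mean-profile (naively pooled) NCA is used throughout, matching the
n = 3/time-point destructive design; no per-animal variance is propagated.

### Derived comparisons

Tissue/plasma AUC ratios, multiple-dose:single-dose accumulation ratios,
oral bioavailability \(F = (\mathrm{AUC}_{PO}/D_{PO}) /
(\mathrm{AUC}_{IV}/D_{IV})\) (values above 1 are reported as-is and
flagged), molar conversion (ng/mL divided by MW in g/mol gives µM; solid
tissue taken at density 1 g/mL, so 6 200 ng/g of a MW-474.6 compound is
13.1 µM), and ordinary least-squares dose-proportionality fits with
\(R^2\). Report tables round tissue/plasma ratios to the nearest integer
and accumulation ratios to one decimal (half-up), the precision at which
such tables are conventionally printed; parameters are otherwise shown at
three significant figures. `NC` marks a parameter that could not be
calculated (terminal phase not estimable, interval not covered), `NA` one
that does not apply to the route (clearance and \(V_{d,ss}\) outside IV
plasma).

### BLQ handling

The assay's lower limits of quantitation are 1.0 ng/mL (plasma) and
5.0 ng/g (liver homogenate; tumor and spleen inherit the liver value as the
same homogenate assay). The default censoring rule is common NCA practice:
below-limit samples before \(T_{max}\) are set to 0, after \(T_{max}\) they
are dropped so they cannot flatten the terminal slope. `drop_all` and
`zero_all` policies are available; the rule is idempotent and a profile
that censors to nothing is an error rather than a silent zero.

## The synthetic study generator

`pk_sim_spec()` + `simulate_study()` generate data with the statistical
structure of the emulated program: closed-form 1- or 2-compartment
disposition (Bateman absorption for oral dosing, with the \(k_a = k_e\)
L'Hôpital branch handled), superposition over repeated doses, instantaneous
tissue partitioning \(C_{tissue} = K_p C_{plasma}\) (optionally a
first-order equilibration rate \(k_{tp}\) that delays the tissue peak, a
phenomenological stand-in for target-mediated tumor retention), log-normal
residual error applied per simulated animal and averaged over
`n_per_timepoint` animals, and LLOQ censoring exactly when the mean falls
below the declared limit. The seed is part of the spec — no global random
state — and a fixed spec reproduces byte-identical data.

Default conditions are the study's own: CL 48 mL/min/kg, \(V_{ss}\)
17 L/kg, F 0.84, n = 3 per time point, residual CV 15 % (the bioanalytical
QC variance was ≤ 5.1 %, so 15 % total allows for biological spread between
animals), \(K_p\) 19/33/44 for tumor/spleen/liver, and the program's
serial-sacrifice grids (`sampling_grids()`). Of the 2-compartment
parameters only CL and \(V_{ss}\) are pinned by the reference values;
\(V_1 = 5\) L/kg and \(Q = 25\) mL/min/kg were chosen once so that the
terminal half-life (~8.9 h) matches the high-dose arm, consistent with the
observed dose-dependent half-life (≈5 h at 3–10 mg/kg vs 8.5 h at
25 mg/kg), which this generator emulates only by re-parameterization:

* the `sd_25`/`md_25` presets use an *apparent* 1-compartment
  parameterization (CL/F 24.3 mL/min/kg derived as F·dose/AUC\(_{0-\infty}\)
  from the reference 25 mg/kg arm, V 17 L/kg, \(k_a\) 0.3 h\(^{-1}\)) that
  reproduces the high-dose profile shape — grid \(T_{max}\) 6 h, \(t_{1/2}\)
  ≈ 9 h, \(C_{max}\) ≈ 750 ng/mL;
* the `chow_10` preset takes its kinetics from the 10 mg/kg single-gavage
  arm (dose/AUC\(_{0-\infty}\) = 34.8 mL/min/kg), consistent with the
  observation that steady-state chow exposure matches single-gavage exposure
  at the same daily dose. Chow intake is modeled as 12 equal mini-boluses
  per day (mouse nibbling), which produces the observed flat profiles; a
  zero-order infusion mode is available and agrees with the bolus train to
  within a few percent in the mean.

What the generator deliberately does **not** capture: nonlinear
(saturable) kinetics, enterohepatic recirculation, and the
beyond-superposition accumulation seen in tumor after 14 daily doses
(MD:SD ratio 5 in tumor vs ~2 elsewhere, plausibly target binding). Linear
superposition cannot produce that ratio, so passing recovery tests show the
NCA machinery is correct on linear kinetics — they do not validate any
mechanism of tumor sequestration.

A recovery experiment (part of the acceptance checks) runs 200 replicate
IV serial-sacrifice studies under these conditions and requires the median
absolute relative error of CL and AUC\(_{0-\infty}\) to stay within 10 %.
With the program's sparse 7-point grid the linear trapezoid overestimates
AUC by ~7 % on the wide 7→24 h segment (a known property of linear
trapezoids on convex decays), so the medians sit near 7–8 % — a faithful
reproduction of the design's own bias, not an artifact of the
implementation. 200 replicates and the 10 000-record marker-filter check
below keep the whole validation suite under half a minute on one CPU.

## The marker-selection filter

The PD filter consumes a per-gene table of *signed* fold changes across
three contrasts — treated vs vehicle tumor (tm/tv), treated vs vehicle
normal pancreas (pm/pv), vehicle pancreas vs vehicle tumor (pv/tv) — and a
p-value. A transcript is selected iff

\[|FC_{tm/tv}| \ge 3 \;\wedge\; |FC_{pm/pv}| < 2 \;\wedge\;
FC_{tm/tv}\cdot FC_{pv/tv} > 9 \;\wedge\; p < 0.001,\]

with strict/non-strict inequalities exactly as stated. The signed
convention (down-regulation of magnitude x encoded as −x, never 1/x) is
load-bearing: the product criterion then selects *concordant* changes —
treatment moves tumor expression in the same direction as the
normal-vs-tumor difference, i.e. toward normalization — and is
unsatisfiable for down-regulated genes under a ratio encoding. Input in
ratio encoding (any |FC| < 1) is rejected as a convention error rather
than silently mis-filtered. The two phrasings of the normal-pancreas
stability requirement ("exclude ≥ 2-fold" and "|FC| < 2") are one
criterion. The p-value cut is applied per record; no additional
multiple-testing correction is layered on top of it. The filter is
deterministic, order-preserving, monotone in each threshold, and tested
against a brute-force per-record predicate evaluation.

PNC prevalence is the fraction of scored cells containing ≥ 1 PNC,
averaged unweighted across samples of a group; groups are compared by a
two-tailed two-sample t-test (pooled variance by default, as appropriate
for a handful of tumors per arm; Welch via `var_equal = FALSE`).
Exposure–response is an OLS regression of relative expression on tumor
AUC\(_{0-24h}\) with \(R^2\) and its two-tailed F-test p-value.

## Numerical choices and edge cases

* Adjusted \(R^2\) tie tolerance \(10^{-4}\) in the λ window search;
  ties favor more points.
* \(T_{max}\) ties go to the earliest time.
* Rounding in report tables is half-up (away from zero), matching how
  36.51 → 37 and 4.96 → 5.0 are conventionally printed; `round()`'s
  banker's rounding would print 2.5 as 2.
* Partial AUC requests outside the sampled range raise an error — there is
  no silent extrapolation.
* Two-point dose-proportionality fits are flagged degenerate
  (\(R^2 = 1\) by construction).
* Equal degenerate groups in the prevalence comparison return p = 1 rather
  than NaN.

## Known limitations and documented discrepancies

* The reference chow-study plasma Cmean is quoted as 0.2 µM in the source
  program, but the stated formula applied to the printed
  AUC\(_{0-24h}\) = 4 160 ng·h/mL gives 173 ng/mL ≈ 0.37 µM. The package
  computes Cmean by the formula and reports the computed value; the
  mismatch is not resolvable from the available numbers and is surfaced
  here rather than hidden.
* Mean-profile NCA understates nothing about the mean but says nothing
  about inter-animal variability; no standard errors are attached.
* \(V_{d,ss}\) on the sparse 7-point IV grid inherits the trapezoidal AUMC
  bias and is recovered only within ~25 % there; the dense-grid tests
  confirm the estimator itself converges to the true volume.
* Compartmental model *fitting* to observed data is out of scope; the
  compartmental machinery exists only to generate synthetic data.
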