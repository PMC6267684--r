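#' Preset simulation specs for the emulated study arms
#'
#' Ready-made [pk_sim_spec()]s reproducing the design and kinetics of each
#' arm of the reference mouse program:
#'
#' * `iv_3`, `po_3`, `po_10` — wild-type arms on the 2-compartment defaults
#'   (CL 48 mL/min/kg, Vss 17 L/kg, F 0.84; ka 0.35/h giving an oral Tmax
#'   near 2 h) with the corresponding serial-sacrifice grids.
#' * `sd_25`, `md_25` — tumor-bearing arms at 25 mg/kg. The high dose shows
#'   slower apparent kinetics (Tmax 6 h, t1/2 ~8.5 h, apparent CL/F lower),
#'   which is emulated by re-parameterization as a 1-compartment model with
#'   apparent clearance 24.3 mL/min/kg (from F*dose/AUCinf of the reference
#'   arm), V 17 L/kg and ka 0.3/h. `md_25` is 14 daily doses with sampling
#'   to 48 h after the last dose.
#' * `chow_10` — steady-state chow feeding at a 10 mg/kg/day equivalent for
#'   14 days, sampled every 3 h over the final day. Kinetics follow the
#'   10 mg/kg single-gavage arm (apparent CL/F 34.8 mL/min/kg = dose/AUCinf
#'   of that arm), consistent with the observation that steady-state chow
#'   exposure matches single-gavage exposure at the same daily dose.
#'
#' @param arm One of `"iv_3"`, `"po_3"`, `"po_10"`, `"sd_25"`, `"md_25"`,
#'   `"chow_10"`.
#' @param seed Integer seed, forwarded to the spec.
#' @param residual_cv Log-normal residual CV (default 0.15).
#' @return A [pk_sim_spec()].
#' @export
preset_sim_spec <- function(arm = c("iv_3", "po_3", "po_10", "sd_25",
                                    "md_25", "chow_10"),
                            seed, residual_cv = 0.15) {
  arm <- match.arg(arm)
  g <- sampling_grids()
  switch(arm,
    iv_3 = pk_sim_spec(dose_regimen("IV", 3), g$iv_single,
                       residual_cv = residual_cv, seed = seed),
    po_3 = pk_sim_spec(dose_regimen("PO_gavage", 3), g$po_single_wt,
                       residual_cv = residual_cv, seed = seed),
    po_10 = pk_sim_spec(dose_regimen("PO_gavage", 10), g$po_single_wt,
                        residual_cv = residual_cv, seed = seed),
    sd_25 = pk_sim_spec(dose_regimen("PO_gavage", 25), g$po_single_kpc,
                        n_compartments = 1L, cl = 24.3, v_central = 17,
                        ka = 0.3, residual_cv = residual_cv, seed = seed),
    md_25 = pk_sim_spec(dose_regimen("PO_gavage", 25, n_doses = 14L),
                        g$po_multi_kpc, n_compartments = 1L, cl = 24.3,
                        v_central = 17, ka = 0.3,
                        residual_cv = residual_cv, seed = seed),
    chow_10 = pk_sim_spec(dose_regimen("PO_chow", 10, n_doses = 14L),
                          g$chow_steady_state, n_compartments = 1L,
                          cl = 34.8, v_central = 17, ka = 0.3, f_oral = 1,
                          residual_cv = residual_cv, seed = seed))
}
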