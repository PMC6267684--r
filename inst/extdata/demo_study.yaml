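# Demo study configuration: the reference mouse program.
# Arms refer to rows of reference_pk_parameters.csv (arm_id/matrix).
analyte:
  name: metarrestin
  molecular_weight: 474.6
  lloq:
    plasma: 1.0
    liver: 5.0
    tumor: 5.0
    spleen: 5.0
arms:
  - {arm_id: iv_3,  route: IV,        dose: 3}
  - {arm_id: po_3,  route: PO_gavage, dose: 3}
  - {arm_id: po_10, route: PO_gavage, dose: 10}
  - {arm_id: sd_25, route: PO_gavage, dose: 25}
  - {arm_id: md_25, route: PO_gavage, dose: 25, n_doses: 14}
  - {arm_id: chow_10, route: PO_chow, dose: 10, n_doses: 14}
comparisons:
  - {kind: tissue_plasma, metric: auc_0_inf, numerator: po_3/liver,  denominator: po_3/plasma}
  - {kind: tissue_plasma, metric: auc_0_inf, numerator: po_10/liver, denominator: po_10/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: sd_25/tumor,  denominator: sd_25/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: sd_25/spleen, denominator: sd_25/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: sd_25/liver,  denominator: sd_25/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: md_25/tumor,  denominator: md_25/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: md_25/spleen, denominator: md_25/plasma}
  - {kind: tissue_plasma, metric: auc_0_24,  numerator: md_25/liver,  denominator: md_25/plasma}
  - {kind: accumulation,  metric: auc_0_24,  numerator: md_25/tumor,  denominator: sd_25/tumor}
  - {kind: accumulation,  metric: auc_0_24,  numerator: md_25/spleen, denominator: sd_25/spleen}
  - {kind: accumulation,  metric: auc_0_24,  numerator: md_25/liver,  denominator: sd_25/liver}
  - {kind: accumulation,  metric: auc_0_24,  numerator: md_25/plasma, denominator: sd_25/plasma}
  - {kind: bioavailability, po: po_3/plasma,  iv: iv_3/plasma}
  - {kind: bioavailability, po: po_10/plasma, iv: iv_3/plasma}
  - {kind: dose_proportionality, metric: auc_0_24,
     arms: [po_3/plasma, po_10/plasma, sd_25/plasma]}
  - {kind: dose_proportionality, metric: auc_0_inf,
     arms: [po_3/plasma, po_10/plasma, sd_25/plasma]}
  - {kind: dose_proportionality, metric: c_max,
     arms: [po_3/plasma, po_10/plasma, sd_25/plasma]}
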