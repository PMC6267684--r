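study,arm_id,matrix,route,dose,auc_0_24,auc_0_48,auc_0_inf,t_half,t_max,c_max,cl_p,vd_ss
wt_single,iv_3,plasma,IV,3,1010,,1040,5,,,48,17
wt_single,po_3,plasma,PO_gavage,3,823,,871,5.4,2,55.7,,
wt_single,po_3,liver,PO_gavage,3,66100,,68600,4.7,1,5420,,
wt_single,po_10,plasma,PO_gavage,10,4520,,4790,5.6,2,349,,
wt_single,po_10,liver,PO_gavage,10,276000,,281000,4.1,2,21400,,
kpc_single,sd_25,plasma,PO_gavage,25,12100,,14400,8.5,6,810,,
kpc_single,sd_25,tumor,PO_gavage,25,232000,,,,6,14000,,
kpc_single,sd_25,spleen,PO_gavage,25,396000,,495000,9.7,6,25000,,
kpc_single,sd_25,liver,PO_gavage,25,536000,,653000,9,6,34200,,
kpc_multi,md_25,plasma,PO_gavage,25,31500,38400,39300,8.2,3,2000,,
kpc_multi,md_25,tumor,PO_gavage,25,1150000,1810000,2090000,18,6,65000,,
kpc_multi,md_25,spleen,PO_gavage,25,959000,1220000,1250000,8.2,6,62400,,
kpc_multi,md_25,liver,PO_gavage,25,987050,1290000,1350000,9.6,6,59500,,
kpc_chow,chow_10,plasma,PO_chow,10,4160,,,,,,,
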