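study_id,perpetrator,perp_dose_mg,perp_interval_h,perp_n_doses,perp_note,victim,victim_dose,dose_unit,route,stagger_h,stagger_ambiguous,n,auc_control,auc_induced,auc_unit,ratio_printed,dose_escalated,ratio_mismatch
rif_iv_mdz_01,rifampicin,600,24,6,,midazolam,2,mg,iv_bolus,24,FALSE,8,126,82.4,ng/mL.h,1.53,FALSE,FALSE
rif_iv_mdz_02,rifampicin,600,24,5,,midazolam,1,mg,iv_bolus,12,TRUE,10,28.4,14.8,ng/mL.h,1.92,FALSE,FALSE
rif_iv_mdz_03,rifampicin,600,24,7,,midazolam,0.05,mg_per_kg,iv_bolus,12,FALSE,52,118,52.8,ng/mL.h,2.23,FALSE,FALSE
rif_iv_mdz_04,rifampicin,600,24,5,,midazolam,1,mg,iv_bolus,12,FALSE,6,53.0,25.5,ng/mL.h,2.08,FALSE,FALSE
rif_iv_mdz_05,rifampicin,600,24,7,,midazolam,0.05,mg_per_kg,iv_bolus,12,TRUE,3,89.5,51.8,ng/mL.h,1.73,FALSE,FALSE
rif_iv_mdz_06,rifampicin,600,24,5,,midazolam,1,mg,iv_bolus,24,FALSE,9,72.2,27.4,ng/mL.h,2.64,FALSE,FALSE
rif_iv_nif_01,rifampicin,600,24,7,,nifedipine,0.02,mg_per_kg,iv_bolus,0,FALSE,6,38.1,26.7,ng/mL.h,1.43,FALSE,FALSE
rif_iv_alf_01,rifampicin,600,24,5,,alfentanil,0.015,mg_per_kg,iv_bolus,13,TRUE,6,111,48.2,ng/mL.h,2.31,FALSE,FALSE
rif_iv_alf_02,rifampicin,600,24,5,,alfentanil,0.015,mg_per_kg,iv_bolus,13,TRUE,10,64.8,24.3,ng/mL.h,2.67,FALSE,FALSE
rif_iv_alf_03,rifampicin,600,24,6,,alfentanil,1,mg,iv_bolus,9,TRUE,6,59.0,21.0,ng/mL.h,2.81,FALSE,FALSE
rif_po_mdz_01,rifampicin,600,24,5,,midazolam,15,mg,oral,17,FALSE,10,170,7.00,ng/mL.h,24.3,FALSE,FALSE
rif_po_mdz_02,rifampicin,600,24,5,,midazolam,15,mg,oral,17,FALSE,9,277,4.40,ng/mL.h,63.0,FALSE,FALSE
rif_po_mdz_03,rifampicin,600,24,9,,midazolam,0.075,mg_per_kg,oral,-2,FALSE,18,49.0,6.10,ng/mL.h,8.03,FALSE,FALSE
rif_po_mdz_04,rifampicin,450,24,5,,midazolam,7.5,mg,oral,12,TRUE,4,67.0,3.50,ng/mL.h,19.1,FALSE,FALSE
rif_po_mdz_05,rifampicin,300,12,14,twice daily for 7 days,midazolam,8,mg,oral,0,TRUE,19,79.6,4.55,ng/mL.h,17.5,FALSE,FALSE
rif_po_mdz_06,rifampicin,300,12,14,twice daily for 7 days,midazolam,8,mg,oral,2,FALSE,16,107,6.46,ng/mL.h,16.6,FALSE,FALSE
rif_po_mdz_07,rifampicin,600,24,6,,midazolam,7.5,mg,oral,24,FALSE,8,103,1.60,ng/mL.h,64.3,FALSE,FALSE
rif_po_mdz_08,rifampicin,600,24,28,,midazolam,2,mg,oral,0,FALSE,11,21.4,2.64,ng/mL.h,8.11,FALSE,FALSE
rif_po_mdz_09,rifampicin,600,24,6,,midazolam,3,mg,oral,12,TRUE,10,20.9,1.10,ng/mL.h,19.0,FALSE,FALSE
rif_po_mdz_10,rifampicin,600,24,16,victim dose escalated to 25 mg in induced arm; ratio from oral clearances,midazolam,2,mg,oral,0,FALSE,12,27.1,19.9,ng/mL.h,17.0,TRUE,FALSE
rif_po_mdz_11,rifampicin,600,24,7,victim dose escalated to 6 mg in induced arm; ratio from clearances,midazolam,4,mg,oral,12,FALSE,52,35.8,3.70,ng/mL.h,25.6,TRUE,FALSE
rif_po_apz_01,rifampicin,450,24,4,,alprazolam,1,mg,oral,0,TRUE,4,242,28.4,ng/mL.h,8.53,FALSE,FALSE
rif_po_smv_01,rifampicin,600,24,9,,simvastatin,40,mg,oral,-2,FALSE,18,29.0,2.60,ng/mL.h,11.2,FALSE,FALSE
rif_po_smv_02,rifampicin,600,24,28,,simvastatin,40,mg,oral,0,FALSE,10,17.3,2.40,ng/mL.h,7.21,FALSE,FALSE
rif_po_nif_01,rifampicin,600,24,7,,nifedipine,20,mg,oral,0,FALSE,6,230,18.8,ng/mL.h,12.2,FALSE,FALSE
rif_po_zol_01,rifampicin,600,24,5,,zolpidem,20,mg,oral,17,FALSE,8,1110,332,ng/mL.h,3.34,FALSE,FALSE
rif_po_alf_01,rifampicin,600,24,6,,alfentanil,0.06,mg_per_kg,oral,13,TRUE,10,103,4.70,ng/mL.h,21.9,FALSE,FALSE
rif_po_alf_02,rifampicin,600,24,5,,alfentanil,4,mg,oral,12,TRUE,6,108,6.40,ng/mL.h,16.9,FALSE,FALSE
rif_po_tzm_01,rifampicin,600,24,5,,triazolam,0.5,mg,oral,17,FALSE,10,14.8,0.74,ng/mL.h,20.0,FALSE,FALSE
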