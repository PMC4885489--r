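study_id,perpetrator,perp_dose_mg,perp_interval_h,perp_n_doses,perp_note,victim,victim_dose,dose_unit,route,stagger_h,stagger_ambiguous,n,auc_control,auc_induced,auc_unit,ratio_printed,dose_escalated,ratio_mismatch
cbz_po_smv_01,carbamazepine,300,12,24,200 mg daily 2-day lead-in then 300 mg twice daily 12 days; maintenance phase transcribed,simvastatin,80,mg,oral,0,FALSE,12,0.089,0.023,mg/L.h,3.93,FALSE,TRUE
cbz_po_qnd_01,carbamazepine,400,12,28,200 mg twice daily 2-day lead-in then 400 mg twice daily 14 days; maintenance phase transcribed,quinidine,200,mg,oral,0,TRUE,10,5.12,1.98,mg/L.h,2.57,FALSE,TRUE
cbz_po_zol_01,carbamazepine,400,24,16,,zolpidem,5,mg,oral,0,TRUE,18,0.235,0.102,mg/L.h,2.31,FALSE,FALSE
phy_po_qnd_01,phenytoin,300,24,14,dose titrated to 10-20 ug/mL plasma; nominal 300 mg daily transcribed,quinidine,300,mg,oral,0,TRUE,2,12.6,5.53,mg/L.h,2.28,FALSE,FALSE
phb_po_nif_01,phenobarbital,100,24,8,,nifedipine,20,mg,oral,12,TRUE,15,0.343,0.135,mg/L.h,2.54,FALSE,FALSE
phb_po_qnd_01,phenobarbital,100,24,14,dose titrated to 10-20 ug/mL plasma; nominal 100 mg daily transcribed,quinidine,300,mg,oral,0,TRUE,2,12.0,4.10,mg/L.h,2.92,FALSE,FALSE
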