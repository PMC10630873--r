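name,units,ref_low,ref_high,is_liver_panel
hemoglobin,g/L,130,175,FALSE
white_blood_cell_count,10^9/L,3.5,9.5,FALSE
red_blood_cell_count,10^12/L,4.3,5.8,FALSE
platelet,10^9/L,125,350,FALSE
thrombocytocrit,ratio,0.11,0.28,FALSE
activated_partial_thromboplastin_time,s,25,37,FALSE
prothrombin_time,s,11,14,FALSE
thrombin_time,s,14,21,FALSE
fibrinogen,g/L,2,4,FALSE
international_normalized_ratio,ratio,0.8,1.2,FALSE
uric_acid,umol/L,208,428,FALSE
creatinine,umol/L,57,111,FALSE
urea,mmol/L,3.1,8,FALSE
glucose,mmol/L,3.9,6.1,FALSE
alanine_aminotransferase,U/L,7,40,TRUE
aspartate_aminotransferase,U/L,13,35,TRUE
total_bilirubin,umol/L,3.4,21,TRUE
conjugated_bilirubin,umol/L,,6.8,TRUE
unconjugated_bilirubin,umol/L,1.7,13.7,FALSE
cholinesterase,U/L,5320,12920,FALSE
gamma_glutamyl_transferase,U/L,10,60,FALSE
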