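indicator,dpmas_pre_mean,dpmas_pre_sd,dpmas_post_mean,conventional_pre_mean,conventional_pre_sd,conventional_post_mean
hemoglobin,112.47,22.42,89.53,115.42,31.44,102.91
white_blood_cell_count,9.29,4.99,11.22,9.03,6.06,8.33
red_blood_cell_count,3.98,1.75,2.66,4.19,1.49,3.38
platelet,102.49,66.87,106.27,111.42,80.54,124.33
thrombocytocrit,0.13,0.06,0.15,0.18,0.11,0.17
activated_partial_thromboplastin_time,53.44,10.79,63.41,42.87,11.57,48.39
prothrombin_time,23.71,7.09,25.63,18.83,4.74,21.14
thrombin_time,33.51,33.21,22.25,21.56,3.53,25.20
fibrinogen,1.32,0.5,1.40,2.16,1.45,1.73
international_normalized_ratio,3.21,4.44,2.33,1.64,0.43,1.85
uric_acid,228.38,140.69,239.09,354.37,143.16,271.76
creatinine,109.40,69.88,109.78,131.90,109.8,152.6
urea,8.10,8.8,9.75,8.83,10.98,11.27
glucose,8.47,3.63,6.41,6.87,1.73,5.84
alanine_aminotransferase,689.29,966.99,50.58,601.21,1109.7,247.04
aspartate_aminotransferase,593.71,536.28,76.61,419.21,570.33,310.00
total_bilirubin,375.23,193.41,220.75,205.73,166.14,268.68
conjugated_bilirubin,245.40,146.5,105.27,136.83,134.83,174.74
unconjugated_bilirubin,120.25,94.92,104.04,67.41,55.92,89.22
cholinesterase,3736.25,1493.02,3027.83,4107.52,2203.11,3282.87
gamma_glutamyl_transferase,192.02,224.2,105.41,341.4,324.48,208.43
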