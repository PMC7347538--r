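name,chain_length,reversed,expr_1e5,expr_se_1e5,cpa_1e2,cpa_se_1e2,frac_1e3,frac_se_1e3,intens_1e5,intens_se_1e5,dg_kcal,dg_se_kcal
ShakerB_d135,9,FALSE,60.5,0.15,1.3,0.02,0.15,0.03,3.7,0.02,-11.68,0.10
ShakerB_d120,24,FALSE,58.4,0.29,2.7,0.03,1.89,0.77,8.3,0.03,-11.48,0.28
ShakerB_CL_IS,39,FALSE,53.6,0.31,8.0,0.06,5.21,1.63,10.7,0.01,-11.28,0.26
ShakerB_d94,50,FALSE,49.3,0.15,20.9,0.13,12.07,1.12,18.7,0.01,NA,NA
ShakerB_d83,61,FALSE,76.6,0.97,64.2,0.33,95.80,10.60,44.8,0.01,-10.62,0.17
ShakerB_CL_IL,88,FALSE,68.0,0.84,47.8,0.23,61.80,5.81,36.4,0.01,-10.50,0.29
ShakerB_d40,104,FALSE,77.5,0.98,35.6,0.16,22.99,1.30,26.8,0.01,-10.02,0.21
ShakerA_WT,106,FALSE,56.4,0.15,38.4,0.24,26.27,2.18,26.3,0.01,-10.12,0.07
ShakerB_WT,144,FALSE,54.2,0.36,19.9,0.19,12.29,3.46,15.5,0.01,-9.76,0.24
ShakerB_RCL,144,TRUE,46.9,0.31,17.4,0.10,9.25,0.79,14.8,0.01,-9.65,0.34
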