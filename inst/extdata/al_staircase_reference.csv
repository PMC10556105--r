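step_height_mm,measured_dose_gy,measured_unc_gy,exp_ratio,exp_ratio_unc,sim_ratio,sim_ratio_unc
0,2.9,0.3,NA,NA,NA,NA
3,0.98,0.10,2.96,0.61,3.08,0.06
6,0.49,0.05,5.92,1.22,5.77,0.13
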