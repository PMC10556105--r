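step_height_mm,scanner_dose_gy,scanner_unc_gy,moem_pos1_gy,moem_pos2_gy,exp_ratio,exp_ratio_unc,sim_ratio,sim_ratio_unc
1,2.9,0.3,NA,2.8,1.07,0.23,1.04,0.02
2,2.9,0.3,2.7,2.7,1.11,0.23,1.09,0.02
3,2.9,0.3,2.6,2.6,1.15,0.25,1.13,0.02
4,2.8,0.3,2.5,2.6,1.15,0.25,1.17,0.02
5,2.8,0.3,2.5,2.4,1.20,0.26,1.21,0.02
10,2.32,0.23,2.1,NA,1.43,0.28,1.42,0.02
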