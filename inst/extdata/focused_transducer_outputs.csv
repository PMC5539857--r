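vpp,w_input_mw,p_ac_mw,efficiency_pct,pressure_kpa,beam_diameter_mm,intensity_w_cm2,mech_index
1,2.54,NA,NA,11.0,2.70,NA,0.005
2,10.2,NA,NA,22.9,2.70,NA,0.011
3,22.8,8.50,37.2,34.7,2.70,0.15,0.017
4,40.6,19.9,49.0,53.7,2.70,0.35,0.026
5,63.4,34.8,54.8,61.5,2.70,0.61,0.030
6,91.4,51.0,55.8,77.4,2.70,0.89,0.038
7,124,71.3,57.4,93.3,2.70,1.25,0.046
8,162,93.6,57.6,117,2.70,1.64,0.058
9,206,123,59.8,136,2.70,2.15,0.067
10,254,153,60.3,153,2.70,2.67,0.076
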