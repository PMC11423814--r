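"name","value","units","source","fit_range_lo","fit_range_hi"
"tau_b",14,"h","reconstructed MAP-like",12,16
"tau_p",9,"h","reconstructed MAP-like",6,9
"tau_r",7,"h","reconstructed MAP-like",4,12
"kd_b",0.12,"1/h","reconstructed MAP-like",0.04,0.36
"kd_p",0.25,"1/h","reconstructed MAP-like",0.0833333333333333,0.75
"kd_r",0.35,"1/h","reconstructed MAP-like",0.116666666666667,1.05
"kd_l",0.08,"1/h","reconstructed MAP-like",0.0266666666666667,0.24
"keb0",0.8,"conc/h","reconstructed MAP-like",0.266666666666667,2.4
"kib",0.7,"conc","reconstructed MAP-like",0.233333333333333,2.1
"n_b",2,"","reconstructed MAP-like",NA,NA
"kep0",5,"conc/h","reconstructed MAP-like",1.66666666666667,15
"kab",0.6,"conc","reconstructed MAP-like",0.2,1.8
"kip",0.15,"conc","reconstructed MAP-like",0.05,0.45
"n_p",2,"","reconstructed MAP-like",NA,NA
"zeta",1,"","reconstructed MAP-like",0.333333333333333,3
"keb2_y",0.03,"conc/h","reconstructed MAP-like",0.01,0.09
"kb_y",0.35,"uM","reconstructed MAP-like",0.116666666666667,1.05
"keb2_m",0.02,"conc/h","reconstructed MAP-like",0.00666666666666667,0.06
"kb_m",0.15,"uM","reconstructed MAP-like",0.05,0.45
"kep2_y",0.4,"conc/h","reconstructed MAP-like",0.133333333333333,1.2
"kp_y",1.08,"uM","reconstructed MAP-like",0.36,3.24
"kep2_m",0.15,"conc/h","reconstructed MAP-like",0.05,0.45
"kp_m",0.45,"uM","reconstructed MAP-like",0.15,1.35
"ker2_y",0.9,"conc/h","reconstructed MAP-like",0.3,2.7
"kr_y",0.22,"uM","reconstructed MAP-like",0.0733333333333333,0.66
"ker2_m",0.2,"conc/h","reconstructed MAP-like",0.0666666666666667,0.6
"kr_m",0.3,"uM","reconstructed MAP-like",0.1,0.9
"n_c",2,"","reconstructed MAP-like",NA,NA
"ke_l",1,"","reconstructed MAP-like",0.333333333333333,3
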