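"label","stiffness_kpa","y27_um","cytd_um","lat_um","jas_um","period_mean_h","period_sd_h","amplitude_mean","amplitude_sd"
"glass",1e+07,0,0,0,0,24,0.6,1,0.15
"stiff_19kPa",19,0,0,0,0,24.4,0.7,1.15,0.2
"stiff_1kPa",1,0,0,0,0,25.9,0.9,3.6,0.7
"y27_10uM",1e+07,10,0,0,0,25.3,0.8,2.4,0.5
"cytd_1uM",1e+07,0,1,0,0,25.1,0.9,2.2,0.5
"latb_0.5uM",1e+07,0,0,0.5,0,25,0.8,2,0.5
"jas_0.2uM",1e+07,0,0,0,0.2,24.5,0.8,0.25,0.1
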