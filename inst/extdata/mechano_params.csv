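"name","value","units","source"
"fak_tot",1,"uM","reconstructed baseline"
"k_f",0.015,"1/s","reconstructed baseline"
"k_sf",0.379,"1/s","reconstructed baseline"
"c_e",8,"kPa","reconstructed baseline"
"k_df",0.035,"1/s","reconstructed baseline"
"rho_tot",1,"uM","reconstructed baseline"
"k_fkrho",0.0168,"1/s","reconstructed baseline"
"gamma_fak",20,"uM^-5","reconstructed baseline"
"n_fak",5,"","reconstructed baseline"
"k_drho",0.625,"1/s","reconstructed baseline"
"rock_tot",1,"uM","reconstructed baseline"
"k_rrho",0.648,"1/uM/s","reconstructed baseline"
"k_drock",0.8,"1/s","reconstructed baseline"
"mdia_tot",0.8,"uM","reconstructed baseline"
"k_mr",0.002,"1/uM/s","reconstructed baseline"
"k_dmdia",0.005,"1/s","reconstructed baseline"
"k_rock_half",0.3,"uM","reconstructed baseline"
"n_rock",2,"","reconstructed baseline"
"k_mdia_half",0.1,"uM","reconstructed baseline"
"n_mdia",2,"","reconstructed baseline"
"myo_tot",5,"uM","reconstructed baseline"
"k_my",0.035,"1/s","reconstructed baseline"
"xi_myo",8,"","reconstructed baseline"
"k_dmy",0.067,"1/s","reconstructed baseline"
"limk_tot",2,"uM","reconstructed baseline"
"k_lk",0.07,"1/s","reconstructed baseline"
"xi_limk",8,"","reconstructed baseline"
"k_dl",2,"1/s","reconstructed baseline"
"cof_tot",2,"uM","reconstructed baseline"
"k_turn",0.04,"1/s","reconstructed baseline"
"k_catcof",0.34,"1/s","reconstructed baseline"
"k_mcof",4,"uM","reconstructed baseline"
"actin_tot",17.9,"uM","reconstructed baseline"
"a_poly",1,"","reconstructed baseline"
"k_ra0",0.07,"1/s","reconstructed baseline"
"alpha_mdia",1.3,"","reconstructed baseline"
"k_dep0",0.35,"1/s","reconstructed baseline"
"k_sev",0.8,"1/uM","reconstructed baseline"
"e_c0",0.3,"kPa","reconstructed baseline"
"e_cf",0.4,"kPa/uM","reconstructed baseline"
"lam_tot",1,"uM","reconstructed baseline"
"k_lamdeph",0.06,"1/s","reconstructed baseline"
"k_lam_half",3,"kPa","reconstructed baseline"
"n_lam",2.6,"","reconstructed baseline"
"k_lamphos",0.01,"1/s","reconstructed baseline"
"npc_tot",1,"uM","reconstructed baseline"
"k_npc",0.08,"1/uM^3/s","reconstructed baseline"
"k_rnpc",8,"1/s","reconstructed baseline"
"yap_tot",1.4,"uM","reconstructed baseline"
"k_yphos",0.2,"1/s","reconstructed baseline"
"k_ydephos",0.004,"1/uM^2/s","reconstructed baseline"
"k_yin0",0.0015,"1/s","reconstructed baseline"
"k_yin_npc",0.04,"1/s","reconstructed baseline"
"k_yout",0.01,"1/s","reconstructed baseline"
"lats_mult",1,"","reconstructed baseline"
"mrtf_tot",1,"uM","reconstructed baseline"
"k_mg_half",5,"uM","reconstructed baseline"
"n_mg",2,"","reconstructed baseline"
"k_min0",0.004,"1/s","reconstructed baseline"
"k_min_npc",0.03,"1/s","reconstructed baseline"
"k_mout",0.015,"1/s","reconstructed baseline"
"k_y27_half",1,"uM","reconstructed baseline"
"n_y27",1,"","reconstructed baseline"
"k_bleb_half",2,"uM","reconstructed baseline"
"n_bleb",1,"","reconstructed baseline"
"r_cg",0.15,"1/uM","reconstructed baseline"
"r_fc",0.05,"1/uM","reconstructed baseline"
"r_gl",1,"1/uM","reconstructed baseline"
"a_jas",10,"","reconstructed baseline"
"b_jas",3,"","reconstructed baseline"
"k_jas_half",0.5,"uM","reconstructed baseline"
"area_a0",2500,"um^2","reconstructed baseline"
"k_area",1,"","reconstructed baseline"
"dens_fak_high",0.6,"","reconstructed baseline"
"dens_lats_high",2,"","reconstructed baseline"
"yap5sa_tot",0,"uM","reconstructed baseline"
"lmna_npc_mult",1,"","reconstructed baseline"
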