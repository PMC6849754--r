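site_id,lat,lon,z_m,tg_c,dg_pa,ig_umol_m2_s,ca_ppm
tropical_lowland,-3.25,-60.25,90,27.1,820,950,400
temperate_forest,48.25,8.75,450,14.2,750,620,400
boreal_conifer,61.75,24.25,120,11.8,520,540,400
montane_andes,-16.25,-68.25,3800,9.5,900,1100,400
arid_steppe,38.75,68.25,950,21.4,2400,1050,400
mediterranean,41.25,2.25,150,19.8,1300,880,400
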