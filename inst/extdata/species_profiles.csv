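species,mass_mean_g,mass_se_g,n_mass,jump_propensity,reaction_mean_ms,reaction_se_ms,n_reaction,takeoff_mean_ms,takeoff_se_ms,n_takeoff,takeoff_scramble_mean_ms,speed_mean_ms1,speed_se_ms1,n_speed,angle_mean_deg,angle_se_deg,n_angle,fps
DIME,40,1,48,0.625,22.8,1.2,39,88,8.3,38,126,2.1,0.1,29,39.7,3.4,29,240
DIDE,89,5,27,0.926,18.8,1.5,24,77.8,6.0,24,NA,2.6,0.1,25,35.3,3.8,25,250
DISP,116,3,46,0.739,29.4,1.4,24,101.9,13.5,20,NA,2.4,0.1,27,31.6,3.1,27,240
CHPE,18,1,22,0.909,28.4,2.2,21,58.2,10.5,20,NA,2.2,0.1,19,39.2,3.2,19,240
NEAL,177,21,14,0.071,19.1,1.0,13,152.5,12.3,13,NA,NA,NA,NA,NA,NA,NA,240
OTBE,523,37,23,0.087,36.8,2.1,21,157.7,12.2,19,NA,NA,NA,NA,NA,NA,NA,120
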