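organ,parameter,mean,sd
plant,first_B,3.6,
plant,delay_B,1.0,
plant,max_B,3.5,
plant,first_SB,8.6,
plant,delay_SB,1.0,
plant,delay_RC,7.4,
plant,n_C,3.0,
plant,seed_x,0.0,
plant,seed_y,0.0,
plant,seed_z,-3.0,
plant,simulation_time,28,
plant,succ_l_lateral,0.04,
plant,succ_s_lateral,0.96,
primary,a,0.054,0.012
seminal,a,0.052,0.011
crown,a,0.061,0.016
l-lateral,a,0.025,0.011
s-lateral,a,0.025,0.007
primary,l_b,0.8,0.899
seminal,l_b,2.55,2.333
crown,l_b,3.161,2.454
l-lateral,l_b,2.27,2.433
primary,l_delay,0.212,0.153
seminal,l_delay,0.499,0.364
crown,l_delay,0.194,0.124
l-lateral,l_delay,0.327,0.294
primary,r,3.951,0.766
seminal,r,3.28,1.955
crown,r,2.981,2.693
l-lateral,r,2.951,1.492
s-lateral,r,2.555,2.479
l-lateral,l_max,5.549,3.821
s-lateral,l_max,1.631,1.596
l-lateral,theta,1.194,0.375
s-lateral,theta,1.194,0.375
primary,l_n,0.466,0.045
seminal,l_n,0.847,0.327
crown,l_n,0.847,0.327
l-lateral,l_n,0.833,0.946
stem,a,0.187,0.01
stem,l_n,1.487,0.313
stem,r,0.759,0.876
leaf,r,7.921,2.338
leaf,l_max,38.411,7.88
leaf,theta,0.705,0.306
leaf,delay_lat,3,
leaf,rot_beta,1,
leaf,width_blade,1.638,
leaf,area_max,54.454,
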