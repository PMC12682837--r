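organ,parameter,mean,sd
plant,first_B,3.6,
plant,delay_B,1.0,
plant,max_B,3.5,
plant,first_SB,9.4,
plant,delay_SB,1.0,
plant,delay_RC,6.6,
plant,n_C,3.6,
plant,seed_x,0.0,
plant,seed_y,0.0,
plant,seed_z,-3.0,
plant,simulation_time,28,
plant,succ_l_lateral,0.05,
plant,succ_s_lateral,0.95,
primary,a,0.064,0.017
seminal,a,0.062,0.016
crown,a,0.059,0.02
l-lateral,a,0.024,0.009
s-lateral,a,0.028,0.01
primary,l_b,1.879,2.385
seminal,l_b,3.883,2.432
crown,l_b,7.216,7.564
l-lateral,l_b,1.732,1.441
primary,l_delay,0.481,0.597
seminal,l_delay,0.941,0.784
crown,l_delay,0.666,0.625
l-lateral,l_delay,0.618,0.444
primary,r,3.35,1.252
seminal,r,2.149,1.417
crown,r,2.556,2.902
l-lateral,r,1.763,0.693
s-lateral,r,5.078,4.814
l-lateral,l_max,4.756,2.513
s-lateral,l_max,1.341,1.15
l-lateral,theta,1.262,0.309
s-lateral,theta,1.37,0.346
primary,l_n,0.457,0.085
seminal,l_n,0.519,0.116
crown,l_n,0.628,0.244
l-lateral,l_n,0.459,0.284
stem,a,0.16,0.02
stem,l_n,0.153,0.175
stem,r,0.915,1.034
leaf,r,7.914,2.041
leaf,l_max,42.606,14.001
leaf,theta,0.773,0.055
leaf,delay_lat,3,
leaf,rot_beta,1,
leaf,width_blade,1.681,
leaf,area_max,66.695,
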