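organ,parameter,mean,sd
plant,first_B,4.0,
plant,delay_B,1.0,
plant,max_B,3.5,
plant,first_SB,8.2,
plant,delay_SB,1.0,
plant,delay_RC,6.2,
plant,n_C,3.0,
plant,seed_x,0.0,
plant,seed_y,0.0,
plant,seed_z,-3.0,
plant,simulation_time,28,
plant,succ_l_lateral,0.05,
plant,succ_s_lateral,0.95,
primary,a,0.091,0.01
seminal,a,0.081,0.011
crown,a,0.066,0.003
l-lateral,a,0.03,0.007
s-lateral,a,0.04,0.012
primary,l_b,3.777,5.681
seminal,l_b,1.642,0.814
crown,l_b,3.924,3.025
l-lateral,l_b,1.779,1.392
primary,l_delay,1.743,1.331
seminal,l_delay,0.94,0.535
crown,l_delay,0.666,0.428
l-lateral,l_delay,0.442,0.309
primary,r,4.627,0.486
seminal,r,3.239,1.698
crown,r,4.886,2.583
l-lateral,r,1.742,0.582
s-lateral,r,5.97,5.168
l-lateral,l_max,4.794,2.392
s-lateral,l_max,1.238,1.123
l-lateral,theta,1.413,0.324
s-lateral,theta,1.413,0.324
primary,l_n,0.545,0.187
seminal,l_n,0.773,0.234
crown,l_n,0.754,0.124
l-lateral,l_n,0.48,0.319
stem,a,0.13,0
stem,l_n,1.636,0.126
stem,r,1.129,0.66
leaf,r,10.907,3.005
leaf,l_max,49.124,15.521
leaf,theta,0.739,0.262
leaf,delay_lat,3,
leaf,rot_beta,1,
leaf,width_blade,1.563,
leaf,area_max,71.956,
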