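organ,parameter,mean,sd
plant,first_B,3.0,
plant,delay_B,1.0,
plant,max_B,3.5,
plant,first_SB,9.2,
plant,delay_SB,1.0,
plant,delay_RC,6.3,
plant,n_C,3.4,
plant,seed_x,0.0,
plant,seed_y,0.0,
plant,seed_z,-3.0,
plant,simulation_time,28,
plant,succ_l_lateral,0.05,
plant,succ_s_lateral,0.95,
primary,a,0.067,0.01
seminal,a,0.066,0.01
crown,a,0.066,0.014
l-lateral,a,0.025,0.008
s-lateral,a,0.025,0.008
primary,l_b,3.183,2.236
seminal,l_b,3.969,4.574
crown,l_b,3.473,2.487
l-lateral,l_b,2.854,2.349
primary,l_delay,2.63,0.284
seminal,l_delay,1.038,0.864
crown,l_delay,0.547,0.476
l-lateral,l_delay,0.341,0.305
primary,r,4.417,0.865
seminal,r,2.912,0.644
crown,r,2.29,2.146
l-lateral,r,2.15,0.56
s-lateral,r,5.292,4.982
l-lateral,l_max,6.736,3.546
s-lateral,l_max,0.84,0.452
l-lateral,theta,1.344,0.324
s-lateral,theta,1.396,0.327
primary,l_n,0.536,0.122
seminal,l_n,0.767,0.202
crown,l_n,0.811,0.419
l-lateral,l_n,0.53,0.417
stem,a,0.166,0.014
stem,l_n,1.676,0.214
stem,r,1,0.772
leaf,r,8.8,2.976
leaf,l_max,52.237,17.901
leaf,theta,0.794,0.403
leaf,delay_lat,3,
leaf,rot_beta,1,
leaf,width_blade,1.561,
leaf,area_max,80.683,
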