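organ,parameter,mean,sd
primary,a,0.069,0.003
seminal,a,0.065,0.003
crown,a,0.063,0.007
l-lateral,a,0.026,0.002
s-lateral,a,0.030,0.002
primary,l_b,2.410,2.033
seminal,l_b,3.011,1.546
crown,l_b,4.444,2.468
l-lateral,l_b,2.159,0.564
primary,l_delay,1.267,0.527
seminal,l_delay,0.855,0.230
crown,l_delay,0.518,0.210
l-lateral,l_delay,0.432,0.071
primary,r,4.086,0.317
seminal,r,2.895,0.567
crown,r,3.178,0.319
l-lateral,r,2.152,0.444
s-lateral,r,4.724,1.263
l-lateral,l_max,5.459,0.721
s-lateral,l_max,1.263,0.472
l-lateral,theta,1.303,0.029
s-lateral,theta,1.343,0.023
primary,l_n,0.501,0.060
seminal,l_n,0.727,0.087
crown,l_n,0.760,0.125
l-lateral,l_n,0.576,0.308
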