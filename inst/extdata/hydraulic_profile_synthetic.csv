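type,age,kr,kx
primary,0,6.0e-5,0.010
primary,5,4.8e-5,0.030
primary,10,3.0e-5,0.080
primary,15,1.8e-5,0.150
primary,20,1.2e-5,0.250
primary,30,9.0e-6,0.300
seminal,0,6.0e-5,0.010
seminal,5,4.8e-5,0.030
seminal,10,3.0e-5,0.080
seminal,15,1.8e-5,0.150
seminal,20,1.2e-5,0.250
seminal,30,9.0e-6,0.300
crown,0,6.0e-5,0.015
crown,5,4.8e-5,0.045
crown,10,3.0e-5,0.120
crown,15,1.8e-5,0.220
crown,20,1.2e-5,0.350
crown,30,9.0e-6,0.400
l-lateral,0,1.2e-4,2.0e-4
l-lateral,3,9.0e-5,5.0e-4
l-lateral,7,6.0e-5,1.0e-3
l-lateral,14,3.6e-5,1.5e-3
l-lateral,30,3.0e-5,2.0e-3
s-lateral,0,1.2e-4,2.0e-4
s-lateral,3,9.0e-5,5.0e-4
s-lateral,7,6.0e-5,1.0e-3
s-lateral,14,3.6e-5,1.5e-3
s-lateral,30,3.0e-5,2.0e-3
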