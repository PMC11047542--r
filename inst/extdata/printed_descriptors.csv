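molecule,eta,sigma,chi,omega,mu
Trolox,2.31,0.432,2.974,1.914,-2.974
Ascorbic acid,2.61,0.383,3.938,2.970,-3.938
RvD1,2.54,0.393,3.500,2.411,-3.500
Analogue 1,2.71,0.369,3.201,1.890,-3.201
Analogue 2,2.56,0.390,3.121,1.902,-3.121
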