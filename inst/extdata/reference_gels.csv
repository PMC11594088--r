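specimen_id,Qv_eq,phi_p0,phi_peq,nu0_NH_um3e6,nu0_AB_um3e6,V1_eq,chi
algGEL_0,2000,0.182,0.008,4.030,0.703,17.777,0.504
algGEL_1,235,0.155,0.077,4.970,0.664,17.755,0.527
ADAGEL_0,2421,0.134,0.006,3.160,0.827,17.777,0.505
ADAGEL_1,220,0.137,0.063,2.915,1.006,17.759,0.522
ADAGEL_2,776,0.140,0.018,4.081,0.566,17.773,0.507
ADAGEL_3,100,0.135,0.133,3.943,1.031,17.737,0.550
ADAGEL_4,417,0.134,0.030,1.812,1.556,17.770,0.510
ADAGEL_5,169,0.126,0.084,3.265,1.156,17.753,0.530
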