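variable,n_A,mean_A,sd_A,se_A,n_B,mean_B,sd_B,se_B,rank_biserial
total,110,6.925,2.716,0.259,21,10.892,0.872,0.190,-0.848
contamination,110,2.322,0.639,0.061,21,4.484,0.408,0.089,-0.935
aerosacculitis,110,0.787,0.490,0.047,21,0.001,0.005,0.001,1.000
contusion,110,1.658,0.670,0.064,21,3.250,0.292,0.064,-0.855
dermatosis,110,0.798,0.375,0.036,21,1.065,0.147,0.032,-0.681
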