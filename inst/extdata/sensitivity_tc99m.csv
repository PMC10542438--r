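isotope,phantom,window,sim,sim_sigma,exp,exp_sigma,ratio,ratio_sigma
Tc-99m,Cylinder,EM,36.33,0.73,37.39,0.33,0.972,0.021
Tc-99m,Cylinder,SC,8.74,0.19,7.865,0.071,1.111,0.026
Tc-99m,NEMA,EM,24.77,0.50,27.06,0.24,0.915,0.020
Tc-99m,NEMA,SC,4.464,0.095,4.376,0.039,1.020,0.023
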