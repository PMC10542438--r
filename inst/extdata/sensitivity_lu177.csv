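isotope,phantom,window,sim,sim_sigma,exp,exp_sigma,ratio,ratio_sigma
Lu-177,Cylinder,EM1,7.63,0.16,8.632,0.043,0.884,0.020
Lu-177,Cylinder,SC1,1.369,0.049,1.647,0.008,0.831,0.030
Lu-177,Cylinder,SC2,1.094,0.042,1.160,0.006,0.943,0.037
Lu-177,Cylinder,EM2,7.15,0.17,8.664,0.043,0.825,0.020
Lu-177,Cylinder,SC3,0.925,0.040,1.201,0.006,0.770,0.034
Lu-177,Cylinder,SC4,0.140,0.006,0.226,0.001,0.622,0.026
Lu-177,NEMA,EM1,6.27,0.14,6.889,0.035,0.910,0.020
Lu-177,NEMA,SC1,1.385,0.05,1.655,0.009,0.837,0.031
Lu-177,NEMA,SC2,0.999,0.039,1.077,0.006,0.928,0.036
Lu-177,NEMA,EM2,5.36,0.13,6.275,0.032,0.855,0.021
Lu-177,NEMA,SC3,0.975,0.043,1.179,0.006,0.827,0.037
Lu-177,NEMA,SC4,0.184,0.008,0.197,0.001,0.935,0.039
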