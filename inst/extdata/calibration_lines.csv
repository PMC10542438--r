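isotope,energy_keV,intensity_percent,intensity_sigma,activity_kBq,activity_sigma,live_time_s
Pb-210,46,4.25,0.04,32.82,0.34,7200
Am-241,60,35.9,0.4,276.2,1.0,600
Ba-133,81,32.9,0.3,129.30,0.88,600
Cd-109,88,3.644,0.016,75.54,0.46,3600
Lu-177,113,6.23,0.04,512.3,2.5,600
Tc-99m,140,89,4,170.6,1.5,600
Te-123m,159,84.0,0.4,58.325,0.085,600
Ce-139,166,79.90,0.04,50.75,0.51,600
Lu-177,208,10.41,0.04,512.3,2.5,600
Ba-133,356,62.05,0.19,129.30,0.88,600
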