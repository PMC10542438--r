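isotope,label,centre_keV,half_width_percent
Tc-99m,EM,140.5,10
Tc-99m,SC_cylinder,119.0,5
Tc-99m,SC_nema,122.5,3
Lu-177,EM1,112.9,10
Lu-177,SC1,98.7,3
Lu-177,SC2,128.1,3
Lu-177,EM2,208.4,10
Lu-177,SC3,182.1,3
Lu-177,SC4,236.3,3
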