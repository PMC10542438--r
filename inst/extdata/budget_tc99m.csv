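component,percent
Capacitance,0.1
Ion chamber reproducibility,0.1
Calibration factor,0.88
Standard error of the mean,0.0104
Voltage change measurement,0.00624
Volume correction,0.00061
Decay correction to reference time,0.01074
Decay correction within measurement (start to middle),0.00326
Decay correction within measurement (end to middle),0.00326
Background,0.01139
Weighing,1.51e-9
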