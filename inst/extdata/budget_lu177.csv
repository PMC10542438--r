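component,percent
Capacitance,0.1
Ion chamber reproducibility,0.1
Calibration factor,0.48
Standard error of the mean,0.0209
Voltage change measurement,0.00441
Volume correction,0.00007
Decay correction to reference time,0.00039
Decay correction within measurement (start to middle),0.00013
Decay correction within measurement (end to middle),0.00013
Background,0.04539
Weighing,3.02e-9
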