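energy_keV,mac_cm2_per_g
10,93.41
15,30.3
20,12.97
30,4.08
40,1.83
50,1.019
60,0.6578
80,0.3656
100,0.2571
150,0.1674
200,0.1376
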