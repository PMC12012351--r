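energy_keV,mac_cm2_per_g
10,20.99
15,6.358
20,2.763
30,0.9306
40,0.4881
50,0.3292
60,0.257
80,0.1951
100,0.1686
150,0.1394
200,0.1245
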