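energy_keV,mac_cm2_per_g
10,15.43
15,4.694
20,2.057
30,0.7197
40,0.3969
50,0.2804
60,0.2268
80,0.1796
100,0.1585
150,0.1335
200,0.1199
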