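energy_keV,mac_cm2_per_g
10,59.5
15,18.9
20,8.06
30,2.56
40,1.187
50,0.7012
60,0.4664
80,0.2881
100,0.2199
150,0.1578
200,0.1347
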