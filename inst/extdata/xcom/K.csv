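energy_keV,mac_cm2_per_g
10,79.06
15,25.43
20,10.92
30,3.413
40,1.541
50,0.8679
60,0.5678
80,0.3251
100,0.2345
150,0.1582
200,0.1319
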