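energy_keV,mac_cm2_per_g
10,40.27
15,12.45
20,5.242
30,1.7
40,0.8096
50,0.4916
60,0.3494
80,0.2324
100,0.1865
150,0.1432
200,0.125
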