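energy_keV,mac_cm2_per_g
10,50.12
15,15.79
20,6.708
30,2.113
40,0.9872
50,0.5849
60,0.4053
80,0.2585
100,0.202
150,0.1506
200,0.1302
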