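energy_keV,mac_cm2_per_g
10,161.5
15,55.12
20,25.46
30,8.561
33.16,6.553
33.18,35.82
40,22.1
50,12.32
60,7.579
80,3.51
100,1.942
150,0.68
200,0.355
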