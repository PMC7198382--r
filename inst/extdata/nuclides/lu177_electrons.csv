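# source=approximate compilation of published ENSDF/ICRP-107 Lu-177 conversion-electron and Auger emissions, 2026-09
# units: energy_MeV, yield (per decay)
"energy_MeV","yield"
0.0476,0.097
0.1017,0.008
0.1107,0.0018
0.1426,0.0335
0.194,0.0065
0.204,0.0015
0.007,0.1
0.001,0.8
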