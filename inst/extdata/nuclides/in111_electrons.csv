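# source=approximate compilation of published ENSDF/ICRP-107 In-111 conversion-electron and Auger emissions, 2026-09
# units: energy_MeV, yield (per decay)
"energy_MeV","yield"
0.1446,0.081
0.1675,0.01
0.2187,0.05
0.2415,0.01
0.0193,0.157
0.0027,1
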