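# source=ENSDF Lu-177 principal gamma and Hf K X-ray lines, 2026-09
# units: energy_keV, yield (per decay)
"energy_keV","yield"
112.95,0.062
208.37,0.1036
321.32,0.0022
55.8,0.047
63.2,0.018
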