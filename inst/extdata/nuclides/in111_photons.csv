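# source=ENSDF In-111 principal gamma and Cd K X-ray lines, 2026-09
# units: energy_keV, yield (per decay)
"energy_keV","yield"
171.28,0.907
245.35,0.941
23.2,0.69
26.1,0.14
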