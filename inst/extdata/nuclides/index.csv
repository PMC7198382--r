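# source=ICRP-107 half-lives (Lu-177: 6.647 d; In-111: 2.8047 d), 2026-09
# units: half_life_h; beta_yield per decay
"name","half_life_h","beta_yield"
"Lu-177",159.528,1
"In-111",67.3128,0
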