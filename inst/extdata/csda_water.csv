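# source=NIST ESTAR CSDA range anchors for liquid water, 2026-09
# units: energy_MeV, csda_g_cm2
"energy_MeV","csda_g_cm2"
0.01,0.0002515
0.015,0.0005147
0.02,0.0008566
0.03,0.001756
0.04,0.002919
0.05,0.00432
0.06,0.00594
0.08,0.00975
0.1,0.01431
0.15,0.02817
0.2,0.04487
0.3,0.08421
0.4,0.1288
0.5,0.1766
0.7,0.278
1,0.4367
1.5,0.7075
2,0.9785
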