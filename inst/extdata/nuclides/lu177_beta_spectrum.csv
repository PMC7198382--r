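# source=allowed-shape Fermi theory from ENSDF Lu-177 branch data (endpoints 497.8/385.0/176.5 keV, intensities 79.4/9.1/11.6 %), generated 2026-09 by data-raw/make_nuclide_tables.R
# units: energy_MeV, density_per_MeV (integrates to 1 over the spectrum)
"energy_MeV","density_per_MeV"
5e-04,5.58700875515283
0.003,5.54089973804618
0.0055,5.49444730297243
0.008,5.44766540607241
0.0105,5.40056796574435
0.013,5.35316912844038
0.0155,5.30548367096667
0.018,5.25752727244014
0.0205,5.20931657019268
0.023,5.16086905430245
0.0255,5.1122028836518
0.028,5.06333668564931
0.0305,5.01428937452575
0.033,4.96508000303938
0.0355,4.91572765054778
0.038,4.86625134444502
0.0405,4.81667000958249
0.043,4.76700243983824
0.0455,4.71726728646223
0.048,4.66748305864294
0.0505,4.61766813262204
0.053,4.56784076649629
0.0555,4.51801911853809
0.058,4.46822126742895
0.0605,4.41846523324407
0.063,4.36876899836916
0.0655,4.31915052779034
0.068,4.2696277883917
0.0705,4.220218767038
0.073,4.17094148732357
0.0755,4.1218140249415
0.078,4.07285452167938
0.0805,4.02408119808169
0.083,3.975512364842
0.0855,3.92716643300163
0.088,3.87906192303821
0.0905,3.83121747293083
0.093,3.78365184528789
0.0955,3.73638393362044
0.098,3.68943276784136
0.1005,3.64281751906418
0.103,3.59655750377192
0.1055,3.55067218741939
0.108,3.5051811875285
0.1105,3.46010427632976
0.113,3.41546138299928
0.1155,3.37127259553516
0.118,3.3275581623135
0.1205,3.28433849335985
0.123,3.24163416136858
0.1255,3.19946590249919
0.128,3.15785461697555
0.1305,3.1168213695116
0.133,3.07638738958399
0.1355,3.03657407157063
0.138,2.99740297477161
0.1405,2.95889582332725
0.143,2.92107450604654
0.1455,2.8839610761578
0.148,2.84757775099184
0.1505,2.81194691160699
0.153,2.77709110236431
0.1555,2.74303303046019
0.158,2.70979556542287
0.1605,2.67740173857869
0.163,2.64587474249301
0.1655,2.61523793039057
0.168,2.58551481555887
0.1705,2.55672907073849
0.173,2.52890452750312
0.1755,2.50206517563212
0.178,2.47603201061588
0.1805,2.44998548160949
0.183,2.42383990495301
0.1855,2.3975993881742
0.188,2.3712680807605
0.1905,2.34485017396096
0.193,2.31834990058519
0.1955,2.29177153480024
0.198,2.26511939192595
0.2005,2.23839782822949
0.203,2.21161124071955
0.2055,2.18476406694085
0.208,2.15786078476912
0.2105,2.13090591220712
0.213,2.10390400718196
0.2155,2.07685966734397
0.218,2.04977752986735
0.2205,2.02266227125292
0.223,1.99551860713292
0.2255,1.96835129207826
0.228,1.9411651194082
0.2305,1.91396492100247
0.233,1.8867555671162
0.2355,1.85954196619741
0.238,1.83232906470731
0.2405,1.80512184694338
0.243,1.77792533486522
0.2455,1.7507445879233
0.248,1.72358470289038
0.2505,1.696450813696
0.253,1.66934809126351
0.2555,1.64228174335011
0.258,1.61525701438953
0.2605,1.58827918533749
0.263,1.56135357351996
0.2655,1.53448553248394
0.268,1.50768045185104
0.2705,1.4809437571736
0.273,1.4542809097933
0.2755,1.42769740670248
0.278,1.40119878040773
0.2805,1.37479059879605
0.283,1.34847846500336
0.2855,1.3222680172853
0.288,1.2961649288904
0.2905,1.27017490793544
0.293,1.24430369728301
0.2955,1.21855707442126
0.298,1.19294085134573
0.3005,1.16746087444319
0.303,1.14212302437758
0.3055,1.11693321597785
0.308,1.09189739812776
0.3105,1.06702155365747
0.313,1.04231169923712
0.3155,1.01777388527203
0.318,0.993414195799762
0.3205,0.969238748388823
0.323,0.945253694039064
0.3255,0.921465217083701
0.328,0.897879535092911
0.3305,0.874502898778964
0.333,0.851341591902904
0.3355,0.828401931182668
0.338,0.805690266202646
0.3405,0.783212979324666
0.343,0.760976485600321
0.3455,0.738987232684651
0.348,0.717251700751127
0.3505,0.695776402407882
0.353,0.674567882615223
0.3555,0.653632718604322
0.358,0.632977519797105
0.3605,0.612608927727293
0.363,0.592533615962552
0.3655,0.572758290027778
0.368,0.55328968732942
0.3705,0.534134577080864
0.373,0.515299760228845
0.3755,0.496792069380847
0.378,0.478618368733487
0.3805,0.460785554001846
0.383,0.443300552349728
0.3855,0.426168055843259
0.388,0.409319877019924
0.3905,0.392725343060711
0.393,0.376389899424315
0.3955,0.360319016280065
0.398,0.344518188455257
0.4005,0.328992935383145
0.403,0.313748801051561
0.4055,0.29879135395219
0.408,0.284126187030428
0.4105,0.269758917635859
0.413,0.255695187473308
0.4155,0.241940662554478
0.418,0.228501033150134
0.4205,0.215382013742853
0.423,0.20258934298029
0.4255,0.190128783628988
0.428,0.178006122528691
0.4305,0.166227170547166
0.433,0.154797762535512
0.4355,0.143723757283955
0.438,0.133011037478111
0.4405,0.12266550965572
0.443,0.112693104163822
0.4455,0.103099775116382
0.448,0.093891500352346
0.4505,0.0850742813941315
0.453,0.076654143406521
0.4555,0.0686371351559759
0.458,0.0610293289703432
0.4605,0.0538368206989623
0.463,0.0470657296731494
0.4655,0.0407221986670633
0.468,0.0348123938589409
0.4705,0.0293425047926959
0.473,0.0243187443398727
0.4755,0.01974734866195
0.478,0.0156345771729882
0.4805,0.0119867125026126
0.483,0.00881006045932578
0.4855,0.00611094999414625
0.488,0.00389573316456337
0.4905,0.00217078509880582
0.493,0.000942503960416732
0.4955,0.000217310913129691
0.498,0
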