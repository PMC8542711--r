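"ring_index","s","semi_width_rel","semi_height_rel"
1,0.02,0.00751897174750743,0.0264013804290283
2,0.04,0.0123138963949664,0.0385714364193153
3,0.06,0.0163590466552642,0.0478638451874956
4,0.08,0.0199298967213726,0.0555090628603551
5,0.1,0.0231399115224673,0.0619991428170877
6,0.12,0.0260491204241625,0.0675933148142824
7,0.14,0.028693849175849,0.0724497151956193
8,0.16,0.0310981073314377,0.0766743102261124
9,0.18,0.0332788390354267,0.0803429849675846
10,0.2,0.0352486552009473,0.0835128713956591
11,0.22,0.0370173821103119,0.086228709088077
12,0.24,0.0385929968519676,0.0885266683946452
13,0.26,0.0399822206955293,0.0904367737689155
14,0.28,0.0411909101805588,0.091984506631846
15,0.3,0.0422243227883862,0.0931919031366647
16,0.32,0.0430873017504003,0.0940783280621908
17,0.34,0.0437844069673681,0.0946610337726078
18,0.36,0.0443200089837725,0.0949555722624942
19,0.38,0.0446983570004297,0.0949761041557281
20,0.4,0.0449236282401181,0.0947356337504954
21,0.42,0.0449999636528124,0.0942461898716175
22,0.44,0.0449314934286969,0.0935189662309783
23,0.46,0.0447223547718774,0.0925644309584627
24,0.48,0.0443767036928296,0.0913924122091835
25,0.5,0.043898722090909,0.0900121648256273
26,0.52,0.0432926210489043,0.0884324216514904
27,0.54,0.0425626410036709,0.0866614320734668
28,0.56,0.0417130492595084,0.0847069895849401
29,0.58,0.0407481351525323,0.0825764495350641
30,0.6,0.039672203038691,0.0802767376832654
31,0.62,0.0384895631519932,0.0778143496688185
32,0.64,0.0372045202503919,0.0751953409761739
33,0.66,0.0358213598208155,0.0724253063712439
34,0.68,0.034344331434489,0.069509347027069
35,0.7,0.0327776286040649,0.0664520225417232
36,0.72,0.0311253641570507,0.0632572836108095
37,0.74,0.0293915396439263,0.0599283789805859
38,0.76,0.0275800065399323,0.0564677270145668
39,0.78,0.0256944157931714,0.0528767369388525
40,0.8,0.0237381502809839,0.0491555560767351
41,0.82,0.0217142313116469,0.0453027042064103
42,0.84,0.0196251841281395,0.0413145285628132
43,0.86,0.0174728355721881,0.0371843598094923
44,0.88,0.0152579929491949,0.0329011394561199
45,0.9,0.0129798994363688,0.0284470417541494
46,0.92,0.0106352278049054,0.0237929891925523
47,0.94,0.00821598777057088,0.0188891257588233
48,0.96,0.00570432460458943,0.0136405350986595
49,0.98,0.00305476193999844,0.00782137461577892
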