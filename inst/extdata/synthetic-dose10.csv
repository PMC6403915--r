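time_days,Mn_g_mol
0,42854.36906
9,38763.34218
18,36426.89428
27,34053.78726
36,30426.45833
45,27843.24626
53,26466.00039
62,24635.02863
71,22347.90712
80,19983.6756
89,18441.46503
98,17278.99305
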