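time_days,Mn_g_mol
0,23467.78174
11,21457.31491
22,18906.11999
32,17917.63642
43,16649.32247
54,15103.16044
65,13617.7013
76,13419.9854
87,11843.34887
97,11445.99573
108,10255.56818
119,9425.346894
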