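time_days,Mn_g_mol
0,64177.94576
10,59656.16247
21,55199.71131
31,49981.36291
41,45734.36342
51,41886.63614
62,37903.62561
72,35344.6405
82,33642.4904
92,30209.88406
103,27508.81454
113,27407.26799
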