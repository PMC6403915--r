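time_days,Mn_g_mol
0,427477.7084
34,361642.8501
68,350960.8902
102,313538.3327
136,298687.7408
170,270041.4323
203,246505.9432
237,234813.4365
271,214466.4997
305,193930.0421
339,174904.9606
373,152711.153
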