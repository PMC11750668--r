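time_min,rate_g_per_min
0,0
30,0.6
60,1.3
90,1.3
120,2.74
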