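w2,tg_K,method
0,328,BDS
0.25,339,BDS
0.5,352,BDS
0.75,365,BDS
1,377,BDS
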