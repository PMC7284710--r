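w2,tg_K,method
0,328,BDS
0.25,321,BDS
0.5,316,BDS
0.75,312,BDS
1,310,BDS
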