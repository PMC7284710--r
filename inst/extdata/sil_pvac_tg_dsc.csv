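w2,tg_K,method
0,331,DSC
0.25,325,DSC
0.5,320,DSC
0.75,316,DSC
1,314,DSC
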