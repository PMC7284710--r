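w2,tg_K,method
0,331,DSC
0.25,342,DSC
0.5,353,DSC
0.75,366,DSC
1,376,DSC
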