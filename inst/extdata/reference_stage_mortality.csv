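max_stage,n,deaths
none,2530,22
stage1,1695,26
stage2,3256,59
stage3,1083,268
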