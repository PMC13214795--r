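stratum,n,n_aki,deaths_aki,deaths_noaki
All,8564,6034,353,22
OPCAB,3990,2593,65,2
ON-CABG,234,201,24,2
Aortic surgery,244,187,18,0
AV-Repair,75,40,1,0
AV-Replacement,733,504,13,1
MV-Repair,472,230,2,0
MV-Replacement,143,109,11,0
TV-Surgery,39,29,3,0
Combined,2423,1984,433,15
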