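sample_id,transcript,qrtpcr_ratio,ddpcr_ratio
DX1,p210,109.3,78
DX2,p210,126.9,109
DX3,p190,71.86,84
DX4,p190,0.08,0.05
DX4,p210,85.61,87.98
DX5,p190,81,71
DX6,p210,103,80
DX7,p190,75,88
DX8,p210,103.6,77
DX9,p190,67.5,79
DX10,p190,63.6,64
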