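label,n_replicates,n_positive,copies_proportional,copies_stated
1e-04,2,2,10,10
5e-05,6,6,5,5
1e-05,8,6,1,2
5e-06,12,2,0.5,1
1e-06,14,2,0.1,0.5
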