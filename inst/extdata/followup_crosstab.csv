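ddpcr_class,qrtpcr_class,count
POS,POS,10
POS,PNQ,29
POS,NEG,7
PNQ,POS,0
PNQ,PNQ,13
PNQ,NEG,4
NEG,POS,0
NEG,PNQ,12
NEG,NEG,13
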