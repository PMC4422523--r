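gene
ATF2
DDX6
DHX9
ELAVL1
HSPA4
NCL
NME1
MED1
RBBP7
DNM1L
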