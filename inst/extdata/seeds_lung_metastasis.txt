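MMP1
RARRES3
FSCN1
ANGPTL4
LTBP1
PTGS2
KYNU
TNC
C10orf116
CXCL1
CXCR4
KRTHB1
VCAM1
LY6E
EREG
NEDD9
MAN1A1
ID1
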