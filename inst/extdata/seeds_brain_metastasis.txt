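MMP1
RARRES3
FSCN1
ANGPTL4
LTBP1
PTGS2
SEPP1
LAMA4
PLOD2
COL13A1
SCNN1A
RGC32
PELI1
TNFSF10
B4GALT6
HBEGF
CSF3
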