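RPS20
LOC112449628
LOC112449630
MOS
PLAG1
FAM110B
LOC101902490
UBXN2B
CYP7A1
TRNAG-CCC
LOC112449629
SDCBP
LOC112449508
NSMAF
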