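target_id,assay_available
HSD17B2,TRUE
HSD17B3,TRUE
ALOX5,TRUE
ACHE,FALSE
AKR1C3,TRUE
AROMATASE,TRUE
PTGS1,TRUE
ESR1,TRUE
ESR2,TRUE
NFKB1,FALSE
PPARG,FALSE
PTPN1,TRUE
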