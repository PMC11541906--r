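ligand	receptor_subunits	pathway
SPP1	CD44	SPP1
SPP1	ITGAV;ITGB1	SPP1
SPP1	ITGAV;ITGB5	SPP1
SPP1	ITGA5;ITGB1	SPP1
MIF	CD74;CXCR4	MIF
MIF	CD74;CD44	MIF
CCL19	CCR7	CCL
CCL21	CCR7	CCL
CXCL12	CXCR4	CXCL
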