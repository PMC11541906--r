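gene	class
PTPRC	pan_immune
CD2	T_cell
CD3D	T_cell
CD3E	T_cell
CD3G	T_cell
CD79A	B_cell
MS4A1	B_cell
CD79B	B_cell
CD68	myeloid
CD14	myeloid
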