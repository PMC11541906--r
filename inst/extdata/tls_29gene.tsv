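gene	class
IGHA1	immunoglobulin
IGHG1	immunoglobulin
IGHG2	immunoglobulin
IGHG3	immunoglobulin
IGHG4	immunoglobulin
IGHGP	immunoglobulin
IGHM	immunoglobulin
IGKC	immunoglobulin
IGLC1	immunoglobulin
IGLC2	immunoglobulin
IGLC3	immunoglobulin
JCHAIN	immunoglobulin
CD79A	B_cell
FCRL5	B_cell
MZB1	B_cell
SSR4	B_cell
XBP1	B_cell
TRBC2	T_cell
IL7R	T_cell
CXCL12	fibroblast
LUM	fibroblast
C1QA	complement
C7	complement
CD52	other
APOE	other
PTLP	other
PTGDS	other
PIM2	other
DERL3	other
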