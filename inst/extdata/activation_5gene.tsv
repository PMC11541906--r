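gene	class
CD79A	B_cell
IGHG1	immunoglobulin
IGHG2	immunoglobulin
IGHG3	immunoglobulin
CCL19	chemokine
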