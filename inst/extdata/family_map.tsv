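gene	family
COL1A1	collagen
COL1A2	collagen
COL2A1	collagen
COL3A1	collagen
COL11A1	collagen
HBA1	hemoglobin_alpha
HBA2	hemoglobin_alpha
HOXA9	homeobox_A
HOXA11	homeobox_A
HOXD11	homeobox_D
PDGFB	pdgf
PDGFA	pdgf
DUSP4	dusp
DUSP6	dusp
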