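gene	protein_change	effect
TP53	R175H	oncogenic
TP53	R273C	oncogenic
TP53	R248Q	oncogenic
HRAS	G13R	oncogenic
HRAS	G12V	oncogenic
KRAS	G12D	oncogenic
NRAS	Q61R	oncogenic
EGFR	T724M	likely_oncogenic
EGFR	L858R	oncogenic
PIK3CA	H1047R	oncogenic
PIK3CA	E545K	oncogenic
BRAF	V600E	oncogenic
CTNNB1	S45F	oncogenic
MDM2	W329G	likely_oncogenic
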