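gene	role
TP53	TSG
RB1	TSG
NF1	TSG
NF2	TSG
MSH2	TSG
MEN1	TSG
CDKN2A	TSG
SPRED1	TSG
SETDB2	TSG
DIS3	TSG
KMT2D	TSG
KMT2C	TSG
ATM	TSG
PTEN	TSG
APC	TSG
SBDS	unassigned
HRAS	oncogene
KRAS	oncogene
NRAS	oncogene
EGFR	oncogene
PDGFB	oncogene
PDGFRA	oncogene
PIK3CA	oncogene
BRAF	oncogene
MDM2	oncogene
CTNNB1	oncogene
MYC	oncogene
EZH2	both
NOTCH1	both
HOXA9	oncogene
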