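gene	role
PDGFB	oncogene
PPARG	oncogene
JAK2	oncogene
NTRK3	oncogene
EGR2	oncogene
ATXN7	oncogene
NCOA2	oncogene
RB1	TSG
NF2	TSG
MSH2	TSG
MEN1	TSG
SPRED1	TSG
CD81	TSG
QKI	TSG
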