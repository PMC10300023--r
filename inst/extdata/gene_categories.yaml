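# Editable gene -> biological category curation used to group putative
# driver variants into 7 categories.
cell cycle and DNA repair:
  - TP53
  - RB1
  - CDKN2A
  - ATM
  - MDM2
  - MSH2
chromatin organization/binding:
  - KMT2D
  - KMT2C
  - EZH2
  - SETDB2
PI3K-Akt-mTOR signaling:
  - PIK3CA
  - PTEN
  - EGFR
  - PDGFB
  - PDGFRA
Wnt signaling:
  - CTNNB1
  - APC
transcription regulator activity:
  - MYC
  - HOXA9
  - NOTCH1
nervous system development:
  - NF1
  - NF2
  - SPRED1
kinase binding:
  - HRAS
  - KRAS
  - NRAS
  - BRAF
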