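# Canonical domain label map: accession -> architecture label.
# Leucine-rich repeat subtypes (single, typical, bacterial, sds22-like, BspA,
# ribonuclease-inhibitor-like) all collapse to LRR; the cysteine-rich
# C-terminal flanking region keeps its own CT label. SP/TM come from the
# Phobius analysis, which reports named features rather than accessions.
labels:
  TIR: [IPR000157]
  LRR: [IPR001611, IPR032675, IPR003591, SM00369, SM00364, SM00365, IPR026906,
        "G3DSA:3.80.10.10"]
  CT: [IPR000483, SM00082]
  MBT: [IPR004092]
  ROC: [IPR020859]
  COR: [IPR032171]
  EF: [IPR002048]
  DEATH: [IPR000488]
  CARD: [IPR031964]
  ARM: [IPR000225, IPR016024, IPR035897]
  NACHT: [IPR007111]
  HELICASE: [IPR011545]
  RLR_CTD: [IPR021673, IPR038557]
  SP: [SIGNAL_PEPTIDE]
  TM: [TRANSMEMBRANE]
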