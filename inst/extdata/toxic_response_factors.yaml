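name: hakanson_lineage
source_note: >
  Dimensionless toxic response factors in the Hakanson (1980) lineage, with
  the customary extensions for elements absent from the original scheme
  (Sb 7 and V 2 as used in later sediment-risk literature; unit factors for
  the low-toxicity lithophiles Zn, Mn, Mo). Editable; every ecological risk
  factor Er = T * Cf flows from this table.
factors:
  Hg: 40
  Cd: 30
  As: 10
  Cu: 5
  Pb: 5
  Ni: 5
  Sb: 7
  Cr: 2
  V: 2
  Zn: 1
  Mn: 1
  Mo: 1
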