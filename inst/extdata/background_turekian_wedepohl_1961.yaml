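name: turekian_wedepohl_1961
source_note: >
  Average shale element concentrations, mg/kg dry weight, after Turekian &
  Wedepohl (1961). Alternative geochemical background; typically less
  sensitive to anthropogenic enrichment than the UCC baseline for As, Cd
  and Sb because the shale standard carries higher natural values for
  those elements.
background:
  Cu: 45
  Cr: 90
  Fe: 47200
  Mn: 850
  Mo: 2.6
  Ni: 68
  V: 130
  Cd: 0.3
  Hg: 0.4
  Pb: 20
  Zn: 95
  Sb: 1.5
  As: 13
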