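name: taylor_mclennan_1995
source_note: >
  Upper continental crust (UCC) average element concentrations, mg/kg dry
  weight, after Taylor & McLennan (1995), as tabulated in the package's
  reference compilation. Used as the default geochemical background for
  contamination factors and derived indices.
background:
  Cu: 45
  Cr: 90
  Fe: 47200
  Mn: 850
  Mo: 2.6
  Ni: 68
  V: 130
  Cd: 0.1
  Hg: 0.4
  Pb: 20
  Zn: 95
  Sb: 0.2
  As: 1.5
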