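name: iris_rais_defaults
source_note: >
  Dose-response constants in the IRIS/RAIS lineage for the five priority
  sediment metals. RfD_ing and RfD_inh are route-specific reference doses
  (mg/kg/day); inhalation values are RfC-derived where an RfC exists
  (RfD_inh = RfC x 20 m3/day / 70 kg). SF_ing is the oral slope factor
  (per mg/kg/day); IUR is the inhalation unit risk pre-converted to
  (mg/kg/day)^-1 (unit risk per ug/m3 x 1000 x 70 kg / 20 m3/day) so
  carcinogenic risk is a plain product with the inhaled dose. GIABS is the
  gastrointestinal absorption fraction; the dermal reference dose is
  derived as RfD_derm = RfD_ing x GIABS unless given explicitly. A null
  SF_ing or IUR means no slope factor exists for that route and the route
  is skipped in carcinogenic risk.
elements:
  As:
    RfD_ing: 3.0e-4
    RfD_inh: 3.0e-4
    GIABS: 1.0
    SF_ing: 1.5
    IUR: 15.1
  Cd:
    RfD_ing: 1.0e-3
    RfD_inh: 2.86e-6
    GIABS: 0.025
    SF_ing: ~
    IUR: 6.3
  Cr:
    RfD_ing: 3.0e-3
    RfD_inh: 2.86e-5
    GIABS: 0.013
    SF_ing: 0.5
    IUR: 42.0
  Ni:
    RfD_ing: 2.0e-2
    RfD_inh: 2.57e-5
    GIABS: 0.04
    SF_ing: ~
    IUR: 0.84
  Pb:
    RfD_ing: 3.5e-3
    RfD_inh: 3.5e-3
    GIABS: 1.0
    SF_ing: 8.5e-3
    IUR: 0.042
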