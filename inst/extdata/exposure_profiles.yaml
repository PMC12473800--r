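name: epa_rags_defaults
source_note: >
  Receptor-specific exposure parameters in the EPA RAGS tradition for
  incidental sediment/soil exposure. ABW body weight (kg); IR sediment
  ingestion rate (mg/day); IHR inhalation rate (m3/day); SA exposed skin
  area (cm2); SAF skin adherence factor (mg/cm2/day); ED exposure duration
  (years); EF_days exposure frequency (days/year); AET_nc and AET_ca
  averaging times (days) for non-carcinogenic (ED x 365) and carcinogenic
  (70-year lifetime) risk; PEF particle emission factor (m3/kg); CFU mass
  conversion (kg/mg). DAF is the dermal absorption fraction per element,
  with a fallback under the key "default".
profiles:
  child:
    ABW: 15
    IR: 200
    IHR: 10
    SA: 2800
    SAF: 0.2
    ED: 6
    EF_days: 350
    AET_nc: 2190
    AET_ca: 25550
    PEF: 1360000000
    CFU: 1.0e-6
    DAF:
      As: 0.03
      default: 0.001
  adult:
    ABW: 70
    IR: 100
    IHR: 20
    SA: 5700
    SAF: 0.07
    ED: 24
    EF_days: 350
    AET_nc: 8760
    AET_ca: 25550
    PEF: 1360000000
    CFU: 1.0e-6
    DAF:
      As: 0.03
      default: 0.001
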