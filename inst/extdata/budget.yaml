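# Default uncertainty budget for the determination of absorbed dose to
# water with the Fricke system at the 20 Gy reference dose.  Components
# are relative (%) standard uncertainties of D_w with unit sensitivity
# coefficients; combine_budget() adds them in quadrature.
coverage_k: 1.0
entries:
  - {label: "Dummy/real source position",             group: "Irradiation Procedure", type_b: 0.1}
  - {label: "Transit time",                           group: "Irradiation Procedure", type_b: 0.016}
  - {label: "Molar extinction coefficient",           group: "Solution Specification", type_b: 0.35}
  - {label: "Density",                                group: "Solution Specification", type_a: 0.100, type_b: 0.100, reference: "Manufacture"}
  - {label: "Source-solution distance",               group: "Solution Specification", type_a: 0.01,  type_b: 0.02,  reference: "Manufacture"}
  - {label: "Dose determination",                     group: "Reading Process", type_a: 0.48, reference: "Manufacture"}
  - {label: "Cuvette-light path",                     group: "Reading Process", type_a: 0.05, type_b: 0.06, reference: "Manufacture"}
  - {label: "Instrument stability",                   group: "Reading Process", type_b: 0.10}
  - {label: "Instrument repeatability",               group: "Reading Process", type_b: 0.10}
  - {label: "Wavelength bandwidth",                   group: "Reading Process", type_b: 0.01}
  - {label: "Solution temperature",                   group: "Reading Process", type_a: 0.010, type_b: 0.15, reference: "Manufacture"}
  - {label: "G(Fe3+) value",                          group: "Correction Factors", type_b: 1.12}
  - {label: "p_wall",                                 group: "Correction Factors", type_a: 0.3, type_b: 0.2}
  - {label: "Volume averaging",                       group: "Correction Factors", type_a: 0.2, type_b: 0.2}
  - {label: "k_dd",                                   group: "Correction Factors", type_a: 0.1, type_b: 0.2}
  - {label: "Dose conversion factor for Fricke to water f", group: "Correction Factors", type_a: 0.2, type_b: 0.2}
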