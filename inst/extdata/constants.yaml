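# Packaged physical constants for the Fricke -> dose-to-water chain.
# Every value is user-overridable by supplying an alternative file of the
# same layout to load_constants().
fricke:
  epsilon_L_per_mol_cm: 2174.0      # molar linear absorption coefficient of Fe3+ at 304 nm
  density_g_per_cm3: 1.023          # Fricke solution density at 25 C
  g_value_mol_per_J: 1.555e-6       # energy-weighted ferric yield for Ir-192
  g_value_u_mol_per_J: 0.017e-6     # its standard uncertainty

let_ir192:
  linear_fit_keV_per_um: 1.28       # LET from first-order energy-vs-LET fit
  quadratic_fit_keV_per_um: 1.237   # LET from second-order fit

# Two-factor multiplicative temperature correction referenced to 25 C
# (literature defaults; per-degree-Celsius fractional coefficients).
temperature_coefficients:
  irradiation_per_C: 0.0012
  reading_per_C: 0.0069

correction_factors:
  f:      {value: 1.004, u: 0.003}  # Fricke-to-water dose conversion
  p_wall: {value: 0.999, u: 0.004}  # PMMA vessel wall perturbation
  f_h:    {value: 0.996, u: 0.003}  # volume-averaging (homogeneity)
  k_dd:   {value: 1.000, u: 0.002}  # dose-profile non-uniformity

tg43:
  lambda_cGy_per_h_per_U: 1.108     # dose rate constant for the microSelectron source
  lambda_rel_u_percent: 0.13

# Quartic ln(LET) coefficients for the primary radiolysis species of
# aerated 0.4 M H2SO4.  Stored on the published column scales:
# alpha1..alpha3 are x 1e-2, alpha4 is x 1e-3; load_constants() expands them.
radiolysis_coefficients:
  H:
    alpha0: 3.601
    alpha1_e2: -13.53
    alpha2_e2: -5.974
    alpha3_e2: -1.929
    alpha4_e3: -4.979
  OH:
    alpha0: 2.766
    alpha1_e2: -18.80
    alpha2_e2: -8.239
    alpha3_e2: -2.127
    alpha4_e3: -4.637
  H2O2:
    alpha0: 0.8438
    alpha1_e2: 5.682
    alpha2_e2: 2.169
    alpha3_e2: 0.6284
    alpha4_e3: 1.988
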