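---
title: "Fricke dosimetry of HDR Ir-192 sources: models, corrections and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fricke dosimetry of HDR Ir-192 sources: models, corrections and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frickedose)
```

## The measurement problem

High-dose-rate (HDR) brachytherapy with Ir-192 sources has no widely
deployed primary standard for the quantity *absorbed dose to water*: the
clinical chain goes through an air-kerma-strength calibration and the
TG-43 formalism, which is indirect. Ferrous-sulfate (Fricke) chemical
dosimetry offers a nearly water-equivalent direct measurement: ionizing
radiation oxidizes Fe^2+ to Fe^3+ in acidic aerated solution, and the
ferric concentration is read spectrophotometrically at 304 nm. This
package implements the complete data-reduction chain for such a
standard, plus the radiolysis model behind its central constant and a
synthetic-experiment generator used to validate the chain end-to-end.

## From absorbance to dose

**Net optical density.** Each irradiation produces replicate cuvette
readings of the irradiated solution and one control (same solution,
same residence time in the vessel, not irradiated). The dose-induced
absorbance increase, referenced to 25 °C, is

$$\Delta OD =
\frac{OD_i - OD_c}{\bigl[1 + c_i (T_i - 25)\bigr]\,\bigl[1 + c_r (T_r - 25)\bigr]},$$

one multiplicative factor per temperature: $T_i$ during irradiation and
$T_r$ during the reading. The coefficients $c_i$ and $c_r$ are
*required configuration* with literature defaults 0.0012 °C⁻¹ and
0.0069 °C⁻¹ packaged in `constants.yaml`; they are deliberately never
hard-coded in the formulas, because they are instrument/solution
properties a laboratory may re-determine. `average_replicates()` applies
the correction per replicate, averages, and reports the sample (n−1)
standard deviation of the mean as the run's Type A repeatability in
percent — identical replicates give exactly 0 %, a single replicate
gives `NA`. Negative corrected values are carried through with a
warning, never clamped, so a swapped irradiated/control pair remains
visible to QC (`blank_qc()`, which uses a strict `<` threshold, default
0.01 AU — the photometric accuracy of a bench spectrophotometer).

**Dose to the Fricke solution.** With $\varepsilon$ the molar linear
absorption coefficient of Fe^3+ at 304 nm (default 2174 L mol⁻¹ cm⁻¹),
$\rho$ the solution density (1.023 g cm⁻³ at 25 °C, numerically equal
to kg L⁻¹), $L$ the cuvette path length in cm and $G(\mathrm{Fe^{3+}})$
the radiation chemical yield in mol J⁻¹,

$$D_F = \frac{\Delta OD}{\rho\, L\, \varepsilon\, G(\mathrm{Fe^{3+}})}.$$

This unit regime yields gray directly with no hidden conversion
constants; it is fixed and documented rather than configurable.

**Dose to water.** Four multiplicative corrections, obtained by Monte
Carlo particle transport in the original metrological work and treated
here as calibrated constants with uncertainties:

$$D_w = D_F \cdot f \cdot p_{wall} \cdot F_h \cdot k_{dd}$$

with packaged defaults $f = 1.004(3)$ (Fricke→water medium conversion),
$p_{wall} = 0.999(4)$ (PMMA vessel wall), $F_h = 0.996(3)$
(volume averaging) and $k_{dd} = 1.000(2)$ (dose-profile
non-uniformity). Their product is 0.998984016; re-deriving the factors
by particle transport is out of scope here.

**TG-43 reference.** For cross-checking, the ionometric route at the
1 cm transverse reference point is the point form
$D_w = S_k\,\Lambda\,\Delta t/100$ (cGy → Gy), with the dose rate
constant $\Lambda = 1.108$ cGy h⁻¹ U⁻¹ (0.13 % relative standard
uncertainty) packaged as the default for the microSelectron source
type. No 2D TG-43 quantities (radial dose function, anisotropy) are
modelled: the reference geometry is metadata, and the correction
factors absorb the geometry. `compare_methods()` reports the per-run
ratio $D_w^{Fricke}/D_w^{TG43}$, its mean and spread.

## The G(Fe³⁺) radiolysis model

The chain's dominant constant is the ferric yield. Two routes are
implemented:

1. **Energy-weighted literature value.** The packaged default,
   $G = 1.555(17)\times 10^{-6}$ mol J⁻¹, is a photon-fluence-weighted
   average of published yields over the Ir-192 spectrum. The underlying
   literature G(E) curves are not packaged (they exist only as figures
   in their sources), so this number ships as a constant;
   `weighted_g_value()` implements the generic weighting operation
   (nearest-bin energy matching, default tolerance half a 50 keV grid
   step) for users who supply their own tables.

2. **LET formalism.** Primary-species yields of aerated 0.4 M H₂SO₄
   radiolysis are parameterised as a quartic in the natural logarithm of
   linear energy transfer,
   $G_s(\mathrm{LET}) = \sum_{i=0}^{4} \alpha_{s,i} (\ln \mathrm{LET})^i$
   (molecules per 100 eV, LET in keV µm⁻¹), with packaged coefficients
   for H, OH and H₂O₂. The published coefficient table carries column
   scale factors (×10⁻² for α₁–α₃, ×10⁻³ for α₄); `load_constants()`
   stores them at the printed scale and expands at load time, and a test
   pins the expansion — a guard against silent scale bugs. The ferric
   yield follows from the aerated-Fricke stoichiometry (each H atom
   oxidises three ferrous ions via the HO₂ chain, each OH one, each
   H₂O₂ two):

   $$G(\mathrm{Fe^{3+}}) = 3\,G_H + G_{OH} + 2\,G_{H_2O_2}.$$

   This functional form and combination rule were adopted after
   verifying that they reproduce both published Ir-192 worked values to
   the last printed digit: 15.123 molecules/100 eV at
   LET = 1.28 keV µm⁻¹ and 15.144 at 1.237 (the two LET values come
   from first- and second-order fits of literature LET-vs-energy
   anchors, via `fit_let_curve()`/`interpolate_let()`; the anchor
   values themselves are user-supplied, not packaged). Unit conversion
   uses $1\ \mathrm{molecule}/100\ \mathrm{eV} = 1/(100\,e\,N_A) =
   1.036427\times10^{-7}$ mol J⁻¹. The two routes agree within 1 %, a
   consistency check kept as an acceptance test.

   The parameterisation is supported on LET ∈ [0.2, 10] keV µm⁻¹;
   evaluation outside warns (extrapolation flagged, not forbidden),
   and non-positive LET is a hard error since its logarithm is taken.

## Uncertainty budget

The budget is declarative: labelled components, each a relative (%)
standard uncertainty of $D_w$ with unit sensitivity coefficient, split
into Type A (statistical) and Type B (other) columns.
`combine_budget()` adds every present component in quadrature,

$$u_c = \sqrt{\textstyle\sum_j \bigl(u_{A,j}^2 + u_{B,j}^2\bigr)},$$

with no correlation terms — verified to reproduce the published
combined value of the reference budget, 1.42 % (k = 1), for a 20 Gy
nominal dose. `inject_type_a()` substitutes a run's measured replicate
repeatability for the budget's nominal dose-determination row, which is
how `process_runs()` attaches a per-run combined uncertainty. The Λ
uncertainty (0.13 %) is *not* added to the default budget: the packaged
file reproduces the reference table verbatim, and whether Λ is already
inside one of its rows is not decidable from the source; users who want
it can add an entry to their own budget file.

Rounding conventions: full precision internally; two decimals at
presentation. Note that the published expanded value, 2.84 %, is the
*already-rounded* combined value doubled; the full-precision expansion
is 2.847 %, which rounds to 2.85 %. `expand_uncertainty()` returns the
full-precision product $k \cdot u_c$; tests assert the published
numbers through the sequential-rounding presentation they came from.

## The synthetic-experiment generator

`simulate_run()` inverts the chain: target dose → Fricke dose (divide
by the correction product) → noiseless ΔOD at 25 °C (invert the OD
relation) → re-dress with the two temperature factors at sampled
temperatures, add the control baseline and per-reading noise, and emit
schema-valid reading/irradiation records. Each run is paired with a
source calibration whose irradiation time makes the TG-43 reference
dose equal the target, so both routes can be compared downstream.

Noise enters at the *reading* level so the Type A statistics computed
downstream are honest:

| parameter | default | rationale |
|---|---|---|
| `od_read_sd` | 2.7×10⁻⁴ AU | sized so one determination's repeatability matches the budget's 0.48 % dose-determination row at the 20 Gy reference (ΔOD ≈ 0.069) |
| `path_sd` | 5×10⁻⁴ cm | the stated measurement uncertainty of the cuvette path lengths |
| `t_irr_drift_sd`, `t_read_drift_sd` | 0.2 °C | ≈ the 0.15 % solution-temperature budget row through the 0.0069 °C⁻¹ reading coefficient |
| `control_od_mean`, `control_od_sd` | 0.05 ± 0.002 AU | typical acidic Fricke baseline absorbance at 304 nm |

These defaults are configuration informed by the budget, not measured
truth, and the generator never consumes published uncertainty values as
ground truth. Temperatures are sampled as 25 °C plus Gaussian drift
(irradiations start only after thermal stabilisation in practice, hence
small drift), clamped into the schema's [10, 40] °C validity band.
Determinism is contractual: a campaign seed spawns per-run sub-seeds
(`seed + run index`), and equal seeds give byte-identical output files.
The default campaign grid, 14–40 Gy with 3 runs per dose and 2
replicate readings per run, mirrors a feasibility measurement with an
HDR afterloader (nominal source strength 40 000 U).

What the generator emulates: replicate structure, temperature
correction, baseline subtraction, path-length variation, reading
repeatability, the TG-43 pairing. What it does not: fading (daily
readings of the real system showed none), vessel chemistry, oxygen
depletion and impurity scavenging (the nonlinear failure modes of real
Fricke systems), spectrophotometer drift, and photon transport. Passing
recovery tests therefore validates the *data reduction*, not the
physical realisation of the standard.

## Numerical and design choices

- **Exactness of the noiseless round trip.** Inverting and re-applying
  the chain uses the same constants, so recovery is exact to floating
  point (tests require ≤ 10⁻⁹ Gy across the grid); replicate averaging
  divides by the mean path length, which commutes exactly with the
  per-replicate linear path dependence.
- **Degenerate inputs.** Zero net OD gives zero dose; non-positive mean
  net OD flags the run instead of erroring, so campaign processing
  survives a bad run; a QC reading exactly at the blank threshold fails
  (strict inequality, documented).
- **Polynomial fits.** `fit_let_curve()` uses ordinary least squares on
  a raw polynomial basis; with degree + 1 anchors it interpolates
  exactly (tested against an independent Vandermonde solve), duplicate
  anchor energies are rejected, and a predicted non-positive LET is a
  hard error because the yield model takes its logarithm.
- **Configuration format.** Constants and budgets ship as YAML — a
  structured-text format with a robust installed parser — keeping every
  physical constant user-overridable by path and out of the code.
- **Problem sizes in the test suite.** The stochastic validation uses a
  500-run campaign at 20 Gy for unbiasedness (mean within 3 SEM), a
  4-dose × 25-run campaign for the recovered-vs-true regression slope
  (compatible with 1 within its standard error), and 100 random budgets
  against a brute-force quadrature oracle; these sizes give stable
  checks in seconds on one core.

## Known limitations

- The energy-weighted G value and the four correction factors are
  packaged constants with uncertainties; the package cannot re-derive
  them (their source data are unpublished figures and Monte Carlo
  transport, respectively).
- The published measured-vs-nominal dose comparison cannot be
  reproduced numerically because per-run data were never tabulated;
  `compare_methods()` is validated on synthetic pairs instead.
- No temperature dependence of G, no fading model, no 2D TG-43
  formalism, and no GUM derivative propagation through the dose
  equations — the budget is the tabulated-quadrature kind by design.
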