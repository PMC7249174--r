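---
title: "Methods: co-solvency solubility modeling in cosolvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-solvency solubility modeling in cosolvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosolvr)
```

This vignette documents the models behind `cosolvr`, their assumptions,
the numerical choices made where the design was genuinely open, and what
the synthetic-data generator does and does not emulate.

## The data model

All analyses run on a `solubility_grid`: saturation mole-fraction
solubilities x_e on a (co-solvent mass fraction m) × (temperature T)
design, here the baricitinib (DMSO + water) reference system — eleven
mass fractions (0 to 1 by 0.1) at 298.2, 303.2, 308.2, 313.2 and
323.2 K, 0.1 MPa. Mass fraction is on a solute-free basis; mole fractions
are computed from weighed masses and molar masses, with the reference
system's published molar masses (371.41, 78.13, 18.07 g/mol) as defaults.
The published water value 18.07 g/mol is slightly off the standard
18.015; we keep the published value as default for reproduction fidelity
and accept user-supplied constants everywhere.

Validation rejects x outside the open interval (0, 1) instead of
clamping: every downstream model works on ln x or log₁₀ x, and a clamped
0 or 1 would silently corrupt those transforms. Duplicated (m, T) design
points are rejected; thermodynamic fits additionally require at least
two (van't Hoff) or three (Apelblat) distinct temperatures.

One cell of the published reference table, (m = 0.2, T = 323.2 K),
printed as 7.05 × 10⁻⁵, is treated as a power-of-ten slip and stored as
7.05 × 10⁻⁴ by default. Two independent arguments support this: it is
the single violation of the otherwise universal monotone increase of
solubility with temperature (55 cells, 11 series), and the published
van't Hoff coefficients of that very series (a = 16.31, b = −7610.3)
predict ≈ 7.2 × 10⁻⁴ at 323.2 K. With the corrected cell our refit of
the series reproduces those published coefficients to four significant
figures; with the verbatim cell it does not. The correction is recorded
in the grid's provenance notes, and `reference_grid(corrected = FALSE)`
returns the verbatim table.

## Ideal solubility and activity coefficients

Ideal solubility uses the two-term fusion expression (fusion enthalpy
plus heat-capacity correction); the gas constant is fixed at
R = 8.314 J/mol/K, consistent with the quantities derived in the source
study, and is deliberately not configurable. Fusion defaults for
baricitinib: T_fus = 487.42 K, ΔH_fus = 41.11 kJ/mol (stored in J/mol
internally), ΔC_p = 84.34 J/mol/K. Activity coefficients are the plain
ratio γ = x^idl/x_e; no non-ideal activity model (UNIFAC, NRTL) is
attempted. Computation keeps full precision; rounding to the two
decimals conventional in published tables happens only in the report
writer. Recomputed values can differ from published ones in the final
printed digit (e.g. 1.548 × 10⁻² vs printed 1.54 × 10⁻²), since the
original intermediate precision is unknown; tests therefore use ~1 %
tolerances on such cells.

## Apparent thermodynamics at the harmonic-mean temperature

Each composition series is regressed as ln x_e on (1/T − 1/T_hm) with
T_hm = n/Σ(1/T) (308.96 K for the reference design). Centering at T_hm
rather than regressing on raw 1/T leaves the slope (hence ΔH)
unchanged but makes the intercept directly proportional to ΔG — the
regression basis is a design choice with no effect on the enthalpy. The
entropy is defined as ΔS = (ΔH − ΔG)/T_hm, so that identity holds to
machine precision by construction. The analysis assumes solution
ideality over the temperature window (hence "apparent" thermodynamics)
and linearity of ln x in 1/T, which the reference data support
(R² ≥ 0.994 in all series).

The compensation analysis regresses ΔH on ΔG across compositions by
*unweighted* OLS. The source description mentions "weighted graphs"
without specifying weights; unweighted OLS on the published
thermodynamic table reproduces the published slope (0.64) exactly, so
that is the implemented convention. Note a reproducibility subtlety:
the published table itself is not exactly recoverable from the rounded
published solubilities — the water-series ΔH recomputes ≈ 1.7 % low
(63.7 vs 64.85 kJ/mol), presumably because the original fits used
unrounded replicate-level data, and consequently the compensation slope
recomputed from our own fits is 0.61. The package therefore ships the
published table as `reference_thermo()` (printed tables are data), and
the report's JSON carries both slopes: `compensation` (recomputed from
the grid) and `compensation_published_reference` (on the published
table). ΔG values, which depend only on the intercept at T_hm, are
robust to the rounding and reproduce to ≤ 0.5 %.

## The five co-solvency models

Log conventions follow the source forms exactly: natural log for van't
Hoff, Apelblat and both Jouyban–Acree forms; base-10 for
Yalkowsky–Roseman.

**Van't Hoff** and **Apelblat** are per-series temperature correlations.
The Apelblat model is linear in (A, B, C), so it is fit by least squares
in the basis (1, 1/T, ln T) rather than by iterative nonlinear search.
Over a 25 K window 1/T and ln T are almost collinear (reciprocal
condition number ~10⁻⁷ on the reference design), so coefficient values
are fragile while predictions are not; model quality should be judged in
prediction space (RMSD), and a conditioning diagnostic is attached to
every fit. Setting `fix_C = 0` recovers the nested van't Hoff model
exactly.

**Yalkowsky–Roseman** is prediction, not fitting: the mixed-cell log
solubility is the mass-fraction blend of the measured pure-solvent
values at the same temperature.

**Jouyban–Acree** estimates the interaction coefficients Jᵢ by
no-intercept least squares of the excess log solubility
(ln x_m − m₁ln x₁ − m₂ln x₂) on the basis functions m₁m₂(m₁−m₂)ⁱ/T,
i = 0..order, with order configurable 0–2 (default 2). Endpoint rows
carry an identically zero basis and excess, so they are dropped from the
regression (they cannot inform J). In the pure form the endpoint terms
are the measured mono-solvent solubilities at each temperature; in the
combined Jouyban–Acree–van't Hoff form they are replaced by the two
endpoint van't Hoff fits, making the model fully parametric in
(A₁, B₁, A₂, B₂, J). The published interaction coefficient for the
reference system (Jᵢ = 82,431) is dimensionally irreconcilable with the
data — at m = 0.5 it would contribute ≈ 69 ln-units where the measured
excess is ≈ 0.006 — and no log-base or scaling convention we tried
reconciles it with the simultaneously published 0.98 % RMSD; our fitted
values ({16.1, −7.6, 28.8}) are reported as-is.

**RMSD convention.** The deviation metric is
100·sqrt(mean(((x_e − x_calc)/x_e)²)) per composition series, and the
overall figure is the unweighted mean of per-series values — the
convention validated by the published Yalkowsky table, whose overall
1.26 % is exactly the mean of its nine per-series values. Which series
enter: all eleven for van't Hoff, Apelblat and the combined
Jouyban–Acree–van't Hoff form; the nine mixed series for
Yalkowsky–Roseman and the pure Jouyban–Acree form, whose endpoint cells
are inputs (reproduced identically) rather than predictions. Published
per-series values are not exactly recoverable (their intermediate
rounding is unknown; deviations up to ~0.9 percentage points occur in
water-rich Yalkowsky series), so the meaningful reproduction claims are
the aggregation convention and the ≤ 5 % overall bound, which all five
models satisfy here (largest: 4.22 %).

## Hansen solubility parameters

Totals are the Euclidean norm of the dispersion/polar/hydrogen-bonding
components; mixtures use the linear blend δ_mix = α·δ₁ + (1−α)·δ₂. The
blending fraction is nominally a volume fraction, but the published
mixture column for DMSO + water is reproduced *exactly* by passing the
mass fraction, so that is the default entry mode; genuine volume
fractions can be passed when densities are known. Component triples for
the solute are user inputs (they were estimated with external
group-contribution software in the source study and are not published).

## The synthetic-data generator

`surface_spec()`/`generate_grid()` define the study conditions for
self-contained testing: the noiseless surface follows the combined
Jouyban–Acree–van't Hoff functional form, and noise is multiplicative
lognormal with unit mean — additive Gaussian on ln x — matching the
log-space least-squares assumption of every model, which makes recovery
tests exact in expectation. Defaults are fixed at the reference system's
magnitudes: endpoint coefficients equal to the published pure-DMSO and
pure-water van't Hoff rows (A₁ = 18.21, B₁ = −6445.3; A₂ = 15.53,
B₂ = −7808.8), the same 11 × 5 design, and noise_cv = 0.02, the order of
the published replicate standard deviations (roughly 1–5 % of each
mean). The default interaction set J = {600, 200, 100} is a modest
positive interaction chosen to sit well above that noise floor so
recovery tests have signal; the real reference system's interaction is
much weaker. Generation is seeded (Mersenne–Twister, seed recorded in
the grid provenance) and does not disturb the caller's RNG stream.

What the generator does *not* emulate: replicate-level triplicate
structure, heteroscedastic or temperature-dependent error, and any
deviation of the true surface from the Jouyban–Acree–van't Hoff form.
Passing recovery tests therefore demonstrates correctness of the
estimators under the models' own assumptions, not robustness to
model misspecification in real data.

## Problem sizes and determinism

All computations are desk-scale: 55-cell grids, five-point regressions,
and a 200-replicate Monte-Carlo recovery study (11 × 5 grids at 2 %
noise) chosen to give standard errors small enough to detect meaningful
bias in J₀ while completing in seconds. The analysis path contains no
randomness, so `run_full_analysis()` is bit-reproducible: two runs on
the same input yield byte-identical JSON.

## Known limitations

- Binary solvent systems only; no ternary co-solvency models
  (CNIBS/R-K, Williams–Amidon, modified Wilson).
- The apparent-thermodynamics interpretation assumes ideality; activity
  corrections are reported (γ) but not propagated into ΔH/ΔG.
- Published-value reproduction is limited by the print precision of the
  source tables, as quantified above; quantities that depend on
  unrounded replicate data (water-series ΔH, per-series RMSD decimals)
  carry documented tolerances.
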