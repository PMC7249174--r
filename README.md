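# cosolvr

Co-solvency solubility modeling and apparent dissolution thermodynamics
for drugs in binary (co-solvent + anti-solvent) mixtures.

Poorly water-soluble drugs are often solubilized by blending water with a
miscible organic co-solvent. Preformulation work then needs the saturation
mole-fraction solubility x(m, T) measured across co-solvent mass fractions
m and temperatures T, condensed into thermodynamic quantities and compact
correlation models. `cosolvr` implements that analysis chain for
pharmaceutical scientists and solution chemists:

- **mole-fraction solubility** from weighed masses,
  x = (m₁/M₁) / (m₁/M₁ + m₂/M₂ + m₃/M₃);
- **ideal solubility** from fusion properties,
  ln x^idl = −ΔH_fus(T_fus−T)/(R·T_fus·T) + (ΔC_p/R)[(T_fus−T)/T + ln(T/T_fus)],
  and **activity coefficients** γ = x^idl / x_e;
- **apparent dissolution thermodynamics** by van't Hoff regression of
  ln x_e on (1/T − 1/T_hm) at the harmonic-mean temperature:
  Δ_sol H⁰ = −R·slope, Δ_sol G⁰ = −R·T_hm·intercept,
  Δ_sol S⁰ = (Δ_sol H⁰ − Δ_sol G⁰)/T_hm;
- **enthalpy–entropy compensation** (OLS of Δ_sol H⁰ on Δ_sol G⁰ across
  compositions);
- **Hansen solubility parameters**: δ² = δ_d² + δ_p² + δ_h² and the linear
  mixture rule δ_mix = α·δ₁ + (1−α)·δ₂;
- **five co-solvency correlation models** compared by percentage RMSD:
  van't Hoff (ln x = a + b/T), modified Apelblat
  (ln x = A + B/T + C ln T), Yalkowsky–Roseman
  (log₁₀ x = m₁ log₁₀ x₁ + m₂ log₁₀ x₂), Jouyban–Acree
  (ln x_{m,T} = m₁ln x₁ + m₂ln x₂ + (m₁m₂/T)ΣJᵢ(m₁−m₂)ⁱ) and the combined
  Jouyban–Acree–van't Hoff form.

The published baricitinib (DMSO + water) solubility surface
(11 compositions × 5 temperatures, 298.2–323.2 K, 0.1 MPa) ships as a
reference dataset, and a seeded synthetic-surface generator supports
parameter-recovery testing of the whole chain without any external data.

## Worked example

```r
library(cosolvr)

g <- reference_grid()
g
#> <solubility_grid> baricitinib in DMSO + water: 55 samples (11 compositions x 5 temperatures)
#>   pressure: 0.1 MPa
#>   note: published mole-fraction solubility table, verbatim values
#>   note: corrected cell (m=0.2, T=323.2 K): printed 7.05e-5 read as power-of-ten typo for 7.05e-4

ideal_solubility(bnb_fusion_properties(), 298.2)
#> [1] 0.00684...      # ideal mole fraction at 298.2 K

s <- g[g$mass_fraction_cosolvent == 1, ]
fit_vant_hoff(s$temperature_K, s$x_exp)
#> <vant_hoff_fit> ln x = 18.2335 -6451.75/T (R2 = 0.9943, RMSD = 4.40%)

thermo_table(g)[c(1, 11), ]
#>   m = 0:  dH = 63.7 kJ/mol, dG = 25.0 kJ/mol, dS = 125 J/mol/K   (pure water)
#>   m = 1:  dH = 53.6 kJ/mol, dG =  6.8 kJ/mol, dS = 152 J/mol/K   (pure DMSO)

compare_models(g)$comparisons
#>   model                  overall_rmsd_percent n_series status
#> 1 vanthoff                               4.10       11 ok
#> 2 apelblat                               2.20       11 ok
#> 3 yalkowsky                              1.69        9 ok
#> 4 jouyban_acree                          1.08        9 ok
#> 5 jouyban_acree_vanthoff                 4.22       11 ok

tab <- reference_thermo()   # published thermodynamic table
compensation_analysis(tab$dH_kJ_mol, tab$dG_kJ_mol)
#> <compensation_fit> dH = 0.641 * dG + 49.091 (R2 = 0.9959, n = 11)
```

Read: dissolution is endothermic and entropy-favoured everywhere
(positive dH and dS), its Gibbs energy falls monotonically from water to
DMSO (solubility rises ~1400-fold at 298.2 K), all five correlation
models stay under 5 % overall RMSD, and the compensation slope of 0.64
(positive, below 1) indicates enthalpy-driven solvation.

`run_full_analysis("reference", out_dir = "report")` writes the complete
bundle (activity, HSP, thermodynamics, compensation and per-model tables
as CSV plus a full-precision `summary.json`); a thin command-line wrapper
lives at `inst/cli/cosolvr.R`. Synthetic surfaces come from
`generate_grid(surface_spec(...))`.

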