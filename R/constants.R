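#' Universal gas constant
#'
#' The molar gas constant used throughout the package, in J/mol/K. It is a
#' fixed physical constant, exposed for transparency rather than
#' configuration: every energy reported by the thermodynamic and model
#' fitting functions scales linearly with it.
#'
#' @format A length-one numeric, 8.314 J/mol/K.
#' @export
R_GAS <- 8.314

#' Reference constants for the baricitinib (DMSO + water) system
#'
#' Published physical constants of the baricitinib / DMSO / water reference
#' system: molar masses, fusion properties and total Hansen solubility
#' parameters. These are the defaults used by [reference_grid()]-based
#' analyses; all of them can be overridden by supplying your own values to
#' the corresponding functions.
#'
#' `bnb_molar_masses()` returns the molar masses (g/mol) of solute
#' (baricitinib, 371.41), co-solvent (DMSO, 78.13) and anti-solvent (water,
#' 18.07). Water's published value of 18.07 g/mol is retained verbatim for
#' reproduction fidelity (the usual 18.015 differs in the third decimal);
#' pass your own list to [mole_fraction()] to use standard values.
#'
#' `bnb_fusion_properties()` returns the fusion properties of baricitinib:
#' fusion temperature 487.42 K, fusion enthalpy 41.11 kJ/mol and heat
#' capacity difference 84.34 J/mol/K.
#'
#' `bnb_hsp()` returns the total Hansen solubility parameters (MPa^0.5) of
#' baricitinib (28.90), DMSO (23.60) and water (47.80).
#'
#' @return A named list (`bnb_molar_masses`, `bnb_hsp`) or a
#'   [fusion_properties()] object (`bnb_fusion_properties`).
#' @seealso [reference_grid()], [reference_thermo()]
#' @export
bnb_molar_masses <- function() {
  list(solute = 371.41, cosolvent = 78.13, antisolvent = 18.07)
}

#' @rdname bnb_molar_masses
#' @export
bnb_fusion_properties <- function() {
  fusion_properties(t_fus = 487.42, dh_fus = 41110, dcp = 84.34)
}

#' @rdname bnb_molar_masses
#' @export
bnb_hsp <- function() {
  list(solute = 28.90, cosolvent = 23.60, antisolvent = 47.80)
}

#' Published apparent dissolution thermodynamics of the reference system
#'
#' The published apparent standard enthalpy, Gibbs energy and entropy of
#' dissolution of baricitinib in the eleven DMSO + water compositions, as
#' tabulated in the source study. These printed values are inputs in their
#' own right: the enthalpy-entropy compensation slope of the reference
#' system is defined on them, and [fit_thermo()] recomputes slightly
#' different enthalpies because only rounded solubilities are published
#' (the replicate-level raw data behind the table is not available).
#'
#' @return A tibble with columns `mass_fraction_cosolvent`, `dH_kJ_mol`,
#'   `dG_kJ_mol`, `dS_J_mol_K` and `r_squared`.
#' @seealso [thermo_table()] for recomputing the same quantities from the
#'   solubility grid, [compensation_analysis()].
#' @export
#' @examples
#' tab <- reference_thermo()
#' compensation_analysis(tab$dH_kJ_mol, tab$dG_kJ_mol)$slope
reference_thermo <- function() {
  tibble::tibble(
    mass_fraction_cosolvent = seq(0, 1, by = 0.1),
    dH_kJ_mol = c(64.85, 63.76, 63.20, 61.87, 60.63, 58.99, 58.02, 57.14,
                  55.83, 54.30, 53.53),
    dG_kJ_mol = c(25.03, 23.18, 21.37, 19.53, 17.71, 15.88, 14.06, 12.24,
                  10.42, 8.60, 6.80),
    dS_J_mol_K = c(128.89, 131.34, 135.39, 137.04, 139.91, 139.50, 142.25,
                   145.30, 146.95, 147.88, 151.23),
    r_squared = c(0.9963, 0.9966, 0.9944, 0.9971, 0.9973, 0.9954, 0.9973,
                  0.9959, 0.9951, 0.9956, 0.9945)
  )
}
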