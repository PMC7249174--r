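#' Fusion properties of a solute
#'
#' Bundles the melting/fusion constants of a crystalline solute needed to
#' compute its ideal solubility: the fusion temperature `t_fus` (K), the
#' fusion enthalpy `dh_fus` (J/mol) and the difference `dcp` (J/mol/K)
#' between the molar heat capacities of the supercooled liquid and the
#' solid.
#'
#' @param t_fus Fusion temperature in K (> 0).
#' @param dh_fus Fusion enthalpy in J/mol (> 0). Note the unit: published
#'   tables usually print kJ/mol.
#' @param dcp Heat capacity difference in J/mol/K (>= 0).
#' @return An object of class `fusion_properties`.
#' @seealso [bnb_fusion_properties()] for the baricitinib values,
#'   [ideal_solubility()]
#' @export
fusion_properties <- function(t_fus, dh_fus, dcp) {
  if (!is.numeric(t_fus) || length(t_fus) != 1 || t_fus <= 0) {
    stop("t_fus must be a positive scalar (K)", call. = FALSE)
  }
  if (!is.numeric(dh_fus) || length(dh_fus) != 1 || dh_fus <= 0) {
    stop("dh_fus must be a positive scalar (J/mol)", call. = FALSE)
  }
  if (!is.numeric(dcp) || length(dcp) != 1 || dcp < 0) {
    stop("dcp must be a nonnegative scalar (J/mol/K)", call. = FALSE)
  }
  structure(list(t_fus = t_fus, dh_fus = dh_fus, dcp = dcp),
            class = "fusion_properties")
}

#' @export
print.fusion_properties <- function(x, ...) {
  cat(sprintf("<fusion_properties> Tfus = %g K, dHfus = %g J/mol, dCp = %g J/mol/K\n",
              x$t_fus, x$dh_fus, x$dcp))
  invisible(x)
}

#' Ideal mole-fraction solubility from fusion properties
#'
#' Computes the ideal solubility of a crystalline solute at temperature T,
#' i.e. the solubility an ideal solution (no excess solute-solvent
#' interactions) would exhibit, from its fusion properties alone:
#'
#' \deqn{\ln x^{idl} = -\frac{\Delta H_{fus}(T_{fus}-T)}{R\,T_{fus}\,T}
#'   + \frac{\Delta C_p}{R}\left[\frac{T_{fus}-T}{T}
#'   + \ln\frac{T}{T_{fus}}\right]}
#'
#' At `T = t_fus` both terms vanish and the result is 1.
#'
#' @param fp A [fusion_properties()] object.
#' @param temperature Absolute temperature(s) in K, each in (0, t_fus\].
#' @return Ideal mole fraction(s) in (0, 1\].
#' @export
#' @examples
#' ideal_solubility(bnb_fusion_properties(), 298.2)  # about 6.84e-3
ideal_solubility <- function(fp, temperature) {
  stopifnot(inherits(fp, "fusion_properties"))
  if (any(temperature <= 0)) {
    stop("temperature must be positive (K)", call. = FALSE)
  }
  if (any(temperature > fp$t_fus)) {
    stop("temperature above the fusion temperature: the solid phase no ",
         "longer limits solubility", call. = FALSE)
  }
  t <- temperature
  lnx <- -fp$dh_fus * (fp$t_fus - t) / (R_GAS * fp$t_fus * t) +
    (fp$dcp / R_GAS) * ((fp$t_fus - t) / t + log(t / fp$t_fus))
  exp(lnx)
}

#' Activity coefficient from ideal and experimental solubility
#'
#' The activity coefficient of the solute in a saturated solution is the
#' ratio of ideal to experimental mole-fraction solubility, gamma =
#' x_ideal / x_exp. Values far above 1 indicate weaker-than-ideal
#' solute-solvent interactions (poor solvents); values below 1 indicate
#' solubilities above the ideal line (strong solute-solvent affinity).
#'
#' @param x_ideal,x_exp Mole fractions in (0, 1\]; vectors recycle.
#' @return Strictly positive activity coefficient(s).
#' @export
activity_coefficient <- function(x_ideal, x_exp) {
  if (any(x_ideal <= 0 | x_ideal > 1) || any(x_exp <= 0 | x_exp > 1)) {
    stop("solubilities must lie in (0, 1]", call. = FALSE)
  }
  x_ideal / x_exp
}

#' Activity coefficients for every sample of a grid
#'
#' Evaluates [ideal_solubility()] at each sample's temperature and divides
#' by the experimental solubility, giving one activity coefficient per
#' (composition, temperature) cell.
#'
#' @param grid A [solubility_grid()].
#' @param fp A [fusion_properties()] object; defaults to the baricitinib
#'   constants.
#' @return A tibble with columns `mass_fraction_cosolvent`,
#'   `temperature_K`, `x_exp`, `x_ideal` and `gamma`, sorted by
#'   composition then temperature.
#' @export
#' @examples
#' act <- activity_table(reference_grid())
#' act[which.max(act$gamma), ]   # pure water, coldest temperature
activity_table <- function(grid, fp = bnb_fusion_properties()) {
  stopifnot(inherits(grid, "solubility_grid"))
  out <- tibble::tibble(
    mass_fraction_cosolvent = grid$mass_fraction_cosolvent,
    temperature_K = grid$temperature_K,
    x_exp = grid$x_exp,
    x_ideal = ideal_solubility(fp, grid$temperature_K)
  )
  out$gamma <- activity_coefficient(out$x_ideal, out$x_exp)
  out[order(out$mass_fraction_cosolvent, out$temperature_K), ]
}
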