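#' Harmonic-mean temperature of a study design
#'
#' The harmonic mean n / sum(1/T_i) of the study temperatures. Centering
#' the van't Hoff regression at this temperature decorrelates the slope
#' and intercept estimates, so the intercept directly yields the apparent
#' Gibbs energy of dissolution.
#'
#' @param temps Positive temperatures in K.
#' @return The harmonic mean in K.
#' @export
#' @examples
#' harmonic_mean_temperature(c(298.2, 303.2, 308.2, 313.2, 323.2))  # 308.96
harmonic_mean_temperature <- function(temps) {
  if (length(temps) == 0) stop("empty temperature set", call. = FALSE)
  if (any(!is.finite(temps)) || any(temps <= 0)) {
    stop("temperatures must be positive and finite", call. = FALSE)
  }
  length(temps) / sum(1 / temps)
}

#' Apparent dissolution thermodynamics of one composition series
#'
#' Fits the van't Hoff regression of ln x on (1/T - 1/T_hm) for a single
#' solvent composition by ordinary least squares and converts the
#' coefficients to apparent standard thermodynamic functions of
#' dissolution, under the solution-ideality assumption of apparent
#' thermodynamic analysis:
#' \deqn{\Delta_{sol}H^0 = -R \cdot slope, \quad
#'       \Delta_{sol}G^0 = -R\,T_{hm} \cdot intercept, \quad
#'       \Delta_{sol}S^0 = (\Delta_{sol}H^0 - \Delta_{sol}G^0)/T_{hm}}
#' The entropy identity holds to machine precision by construction.
#'
#' @param temperature Temperatures in K (>= 2 distinct values).
#' @param x Experimental mole fractions in (0, 1), same length.
#' @param t_hm Harmonic-mean temperature at which to center; defaults to
#'   the harmonic mean of `temperature`.
#' @return An object of class `thermo_fit`: a list with `dH`, `dG` (J/mol),
#'   `dS` (J/mol/K), `r_squared`, `t_hm`, `n_points`.
#' @seealso [thermo_table()] for all compositions of a grid,
#'   [compensation_analysis()]
#' @export
#' @examples
#' s <- reference_grid()
#' s <- s[s$mass_fraction_cosolvent == 1, ]
#' fit_thermo(s$temperature_K, s$x_exp)
fit_thermo <- function(temperature, x,
                       t_hm = harmonic_mean_temperature(temperature)) {
  if (length(temperature) != length(x)) {
    stop("temperature and x must have equal length", call. = FALSE)
  }
  if (length(unique(temperature)) < 2) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  if (any(x <= 0 | x >= 1)) {
    stop("x must lie in the open interval (0, 1)", call. = FALSE)
  }
  z <- 1 / temperature - 1 / t_hm
  fit <- stats::lm(log(x) ~ z)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  dH <- -R_GAS * slope
  dG <- -R_GAS * t_hm * intercept
  structure(list(
    dH = dH, dG = dG, dS = (dH - dG) / t_hm,
    r_squared = r_squared_of(log(x), intercept + slope * z),
    t_hm = t_hm, n_points = length(x),
    slope = slope, intercept = intercept
  ), class = "thermo_fit")
}

#' @export
print.thermo_fit <- function(x, ...) {
  cat(sprintf(paste0("<thermo_fit> dH = %.2f kJ/mol, dG = %.2f kJ/mol, ",
                     "dS = %.2f J/mol/K (Thm = %.2f K, n = %d, R2 = %.4f)\n"),
              x$dH / 1000, x$dG / 1000, x$dS, x$t_hm, x$n_points, x$r_squared))
  invisible(x)
}

#' Apparent dissolution thermodynamics for every composition of a grid
#'
#' Runs [fit_thermo()] on each composition series of a solubility grid at
#' a common harmonic-mean temperature and reports the energies in the
#' units conventional for published tables (kJ/mol for enthalpy and Gibbs
#' energy, J/mol/K for entropy).
#'
#' @param grid A [solubility_grid()].
#' @param t_hm Common centering temperature; defaults to the harmonic mean
#'   of the distinct grid temperatures.
#' @return A tibble with columns `mass_fraction_cosolvent`, `dH_kJ_mol`,
#'   `dG_kJ_mol`, `dS_J_mol_K`, `r_squared`, `t_hm_K`, `n_points`.
#' @export
#' @examples
#' thermo_table(reference_grid())
thermo_table <- function(grid,
                         t_hm = harmonic_mean_temperature(unique(grid$temperature_K))) {
  stopifnot(inherits(grid, "solubility_grid"))
  ms <- grid_compositions(grid)
  rows <- lapply(ms, function(m) {
    s <- grid_series(grid, m)
    f <- fit_thermo(s$temperature_K, s$x_exp, t_hm = t_hm)
    tibble::tibble(mass_fraction_cosolvent = m,
                   dH_kJ_mol = f$dH / 1000,
                   dG_kJ_mol = f$dG / 1000,
                   dS_J_mol_K = f$dS,
                   r_squared = f$r_squared,
                   t_hm_K = f$t_hm,
                   n_points = f$n_points)
  })
  do.call(rbind, rows)
}

#' Enthalpy-entropy compensation analysis
#'
#' Ordinary least-squares regression of the apparent dissolution enthalpy
#' on the apparent dissolution Gibbs energy across solvent compositions,
#' evaluated at the harmonic-mean temperature. A positive slope below 1
#' indicates an enthalpy-driven solvation mechanism; a slope above 1, an
#' entropy-driven one.
#'
#' @param dH,dG Numeric vectors of equal length (any consistent energy
#'   unit; slope is unitless, intercept inherits the unit).
#' @return An object of class `compensation_fit`: list with `slope`,
#'   `intercept`, `r_squared`, `n`.
#' @export
#' @examples
#' tab <- reference_thermo()
#' compensation_analysis(tab$dH_kJ_mol, tab$dG_kJ_mol)
compensation_analysis <- function(dH, dG) {
  if (length(dH) != length(dG)) {
    stop("dH and dG must have equal length", call. = FALSE)
  }
  if (length(unique(dG)) < 2) {
    stop("need at least 2 distinct dG values for the compensation ",
         "regression", call. = FALSE)
  }
  fit <- stats::lm(dH ~ dG)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(
    slope = slope,
    intercept = intercept,
    r_squared = r_squared_of(dH, intercept + slope * dG),
    n = length(dH)
  ), class = "compensation_fit")
}

#' @export
print.compensation_fit <- function(x, ...) {
  cat(sprintf("<compensation_fit> dH = %.3f * dG + %.3f (R2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
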