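#' Specification of a synthetic solubility surface
#'
#' Defines a generative model for a (composition x temperature)
#' solubility grid with the statistical structure the analysis chain
#' assumes: the noiseless surface follows the combined
#' Jouyban-Acree-van't Hoff functional form (see
#' [fit_jouyban_acree()]), and measurement noise is multiplicative
#' lognormal, i.e. additive Gaussian on ln x, matching the log-space
#' least-squares assumption of all five co-solvency models.
#'
#' The defaults mimic the magnitudes of the baricitinib (DMSO + water)
#' reference system: the endpoint van't Hoff coefficients are those of
#' its pure-DMSO and pure-water series, the design is the same 11
#' compositions x 5 temperatures, and the noise coefficient of variation
#' of 0.02 is of the order of the published replicate standard
#' deviations. The default interaction coefficients are a modest
#' positive set chosen to be well above that noise floor, so that
#' parameter-recovery tests have signal to recover.
#'
#' @param A1,B1 Van't Hoff coefficients (intercept, slope in K) of the
#'   pure co-solvent series.
#' @param A2,B2 Same for the pure anti-solvent series.
#' @param j_coeffs Up to three interaction coefficients J0, J1, J2 (K).
#' @param compositions Co-solvent mass fractions in \[0, 1\].
#' @param temperatures Temperatures in K.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (>= 0; 0 means the exact surface).
#' @param seed Integer seed making [generate_grid()] reproducible.
#' @return Object of class `surface_spec`.
#' @export
surface_spec <- function(A1 = 18.21, B1 = -6445.3,
                         A2 = 15.53, B2 = -7808.8,
                         j_coeffs = c(600, 200, 100),
                         compositions = seq(0, 1, by = 0.1),
                         temperatures = c(298.2, 303.2, 308.2, 313.2, 323.2),
                         noise_cv = 0.02, seed = 1L) {
  if (length(j_coeffs) < 1 || length(j_coeffs) > 3) {
    stop("j_coeffs must hold 1 to 3 coefficients", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  if (any(compositions < 0 | compositions > 1)) {
    stop("compositions must lie in [0, 1]", call. = FALSE)
  }
  if (any(temperatures <= 0)) {
    stop("temperatures must be positive", call. = FALSE)
  }
  spec <- structure(list(A1 = A1, B1 = B1, A2 = A2, B2 = B2,
                         j_coeffs = j_coeffs,
                         compositions = sort(unique(compositions)),
                         temperatures = sort(unique(temperatures)),
                         noise_cv = noise_cv, seed = as.integer(seed)),
                    class = "surface_spec")
  # fail early if the spec implies unphysical solubilities
  design <- expand.grid(m = spec$compositions, t = spec$temperatures)
  true_surface(spec, design$m, design$t)
  spec
}

#' @export
print.surface_spec <- function(x, ...) {
  cat(sprintf(paste0("<surface_spec> endpoints (A1,B1)=(%.2f,%.1f) ",
                     "(A2,B2)=(%.2f,%.1f), J=[%s]\n  %d compositions x %d ",
                     "temperatures, noise_cv = %g, seed = %d\n"),
              x$A1, x$B1, x$A2, x$B2,
              paste(x$j_coeffs, collapse = ", "),
              length(x$compositions), length(x$temperatures),
              x$noise_cv, x$seed))
  invisible(x)
}

#' Noiseless solubility surface of a synthetic specification
#'
#' Deterministic evaluation of the generative model at one or more
#' (composition, temperature) points:
#' \deqn{\ln x_{m,T} = m_1(A_1 + B_1/T) + m_2(A_2 + B_2/T) +
#'   \frac{m_1 m_2}{T} \sum_i J_i (m_1 - m_2)^i}
#' At m = 1 this reduces to the pure co-solvent van't Hoff line
#' independent of the interaction coefficients; with all J = 0 the
#' mid-composition value is the geometric mean of the endpoint
#' solubilities.
#'
#' @param spec A [surface_spec()].
#' @param m Co-solvent mass fraction(s) in \[0, 1\].
#' @param temperature Temperatures in K.
#' @return True mole fraction(s), all in (0, 1).
#' @export
true_surface <- function(spec, m, temperature) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- max(length(m), length(temperature))
  m1 <- rep_len(m, n); temps <- rep_len(temperature, n)
  if (any(m1 < 0 | m1 > 1)) stop("m must lie in [0, 1]", call. = FALSE)
  if (any(temps <= 0)) stop("temperature must be positive", call. = FALSE)
  m2 <- 1 - m1
  terms <- vapply(seq_along(spec$j_coeffs), function(k) {
    spec$j_coeffs[k] * m1 * m2 * (m1 - m2)^(k - 1) / temps
  }, numeric(n))
  interaction <- rowSums(matrix(terms, nrow = n))
  x <- exp(m1 * (spec$A1 + spec$B1 / temps) + m2 * (spec$A2 + spec$B2 / temps) +
             interaction)
  if (any(x >= 1)) {
    stop("spec implies mole fractions >= 1: inconsistent surface ",
         "specification", call. = FALSE)
  }
  x
}

#' Generate a noisy solubility grid from a synthetic specification
#'
#' Evaluates the noiseless surface on the full design and multiplies each
#' cell by a lognormal noise factor with unit mean and coefficient of
#' variation `noise_cv` (so noise is additive Gaussian on ln x and
#' unbiased on the natural scale). The generator is seeded from the spec,
#' so the same spec always produces the same grid, and the generator
#' identity and seed are recorded in the grid's provenance notes.
#'
#' @param spec A [surface_spec()].
#' @return A [solubility_grid()] passing full validation.
#' @export
#' @examples
#' g <- generate_grid(surface_spec(noise_cv = 0))
#' fit_jouyban_acree(g, combined_with_vant_hoff = TRUE)$j_coeffs  # 600 200 100
generate_grid <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  design <- expand.grid(temperature_K = spec$temperatures,
                        mass_fraction_cosolvent = spec$compositions)
  x_true <- true_surface(spec, design$mass_fraction_cosolvent,
                         design$temperature_K)
  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log1p(spec$noise_cv^2))
    noise <- withr_seed(spec$seed, function() {
      stats::rlnorm(nrow(design), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    x <- x_true * noise
  } else {
    x <- x_true
  }
  solubility_grid(
    data.frame(mass_fraction_cosolvent = design$mass_fraction_cosolvent,
               temperature_K = design$temperature_K,
               x_exp = x),
    solute = "synthetic solute", cosolvent = "synthetic co-solvent",
    antisolvent = "synthetic anti-solvent",
    provenance = sprintf(
      "synthetic grid: Jouyban-Acree-van't Hoff surface, lognormal noise cv=%g, Mersenne-Twister seed=%d",
      spec$noise_cv, spec$seed)
  )
}

# Run fn under a local RNG seed without disturbing the caller's RNG state.
withr_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  fn()
}
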