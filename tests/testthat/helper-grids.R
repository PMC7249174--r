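# Shared fixtures built in code.

study_temps <- c(298.2, 303.2, 308.2, 313.2, 323.2)

# Minimal two-endpoint grid following exact van't Hoff endpoint lines,
# with mixed cells given by an exact log-linear blend (zero interaction).
blend_grid <- function(compositions = seq(0, 1, by = 0.1),
                       temps = study_temps,
                       A1 = 18, B1 = -6400, A2 = 15, B2 = -7800) {
  design <- expand.grid(mass_fraction_cosolvent = compositions,
                        temperature_K = temps)
  m1 <- design$mass_fraction_cosolvent
  lnx <- m1 * (A1 + B1 / design$temperature_K) +
    (1 - m1) * (A2 + B2 / design$temperature_K)
  solubility_grid(cbind(design, x_exp = exp(lnx)))
}

# Brute-force no-intercept least-squares oracle: explicit normal
# equations, independent of lm / lm.fit.
normal_equations_j <- function(grid, order) {
  m1 <- grid$mass_fraction_cosolvent
  m2 <- 1 - m1
  keep <- m1 > 0 & m1 < 1
  temps <- sort(unique(grid$temperature_K))
  lnx1 <- sapply(grid$temperature_K, function(t) {
    log(grid$x_exp[grid$mass_fraction_cosolvent == 1 &
                     grid$temperature_K == t])
  })
  lnx2 <- sapply(grid$temperature_K, function(t) {
    log(grid$x_exp[grid$mass_fraction_cosolvent == 0 &
                     grid$temperature_K == t])
  })
  y <- log(grid$x_exp) - m1 * lnx1 - m2 * lnx2
  X <- sapply(0:order, function(i) m1 * m2 * (m1 - m2)^i / grid$temperature_K)
  X <- matrix(X[keep, ], ncol = order + 1)
  drop(solve(t(X) %*% X, t(X) %*% y[keep]))
}
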