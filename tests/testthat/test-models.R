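test_that("rmsd_percent matches hand oracles and the published mean convention", {
  expect_equal(rmsd_percent(c(1, 2), c(1, 2)), 0)
  expect_equal(rmsd_percent(c(1, 2), c(1.1, 1.8)), 10)
  # overall RMSD = unweighted mean of the published per-series values
  yal_series <- c(1.47, 1.56, 1.31, 1.25, 1.50, 1.15, 1.23, 1.03, 0.87)
  expect_equal(mean(yal_series), 1.26, tolerance = 5e-3)
  expect_error(rmsd_percent(1:3, 1:2), "equal length")
  expect_error(rmsd_percent(c(0, 1), c(1, 1)), "nonzero")
})

test_that("van't Hoff fit reproduces the published pure-DMSO coefficients", {
  g <- reference_grid()
  s <- g[g$mass_fraction_cosolvent == 1, ]
  f <- fit_vant_hoff(s$temperature_K, s$x_exp)
  expect_equal(f$a, 18.21, tolerance = 5e-3)
  expect_equal(f$b, -6445.30, tolerance = 5e-3)
  expect_gt(f$r_squared, 0.99)
  expect_lt(f$rmsd_percent, 5)
})

test_that("van't Hoff recovers exact lines and interpolates two points", {
  x <- exp(15 - 7000 / study_temps)
  f <- fit_vant_hoff(study_temps, x)
  expect_equal(f$a, 15, tolerance = 1e-9)
  expect_equal(f$b, -7000, tolerance = 1e-9)
  expect_equal(f$rmsd_percent, 0, tolerance = 1e-9)

  f2 <- fit_vant_hoff(c(300, 320), c(1e-4, 5e-4))
  expect_equal(predict(f2, c(300, 320)), c(1e-4, 5e-4), tolerance = 1e-12)
  expect_equal(f2$r_squared, 1)
  expect_error(fit_vant_hoff(300, 1e-4), "distinct")
})

test_that("Apelblat predictions track the reference series closely", {
  g <- reference_grid()
  s <- g[g$mass_fraction_cosolvent == 1, ]
  f <- fit_apelblat(s$temperature_K, s$x_exp)
  expect_true(all(abs(predict(f, s$temperature_K) - s$x_exp) / s$x_exp < 0.02))
  expect_gt(f$r_squared, 0.999)
})

test_that("Apelblat with C constrained to zero is exactly van't Hoff", {
  g <- reference_grid()
  s <- g[g$mass_fraction_cosolvent == 0.5, ]
  vh <- fit_vant_hoff(s$temperature_K, s$x_exp)
  ap <- fit_apelblat(s$temperature_K, s$x_exp, fix_C = 0)
  expect_identical(ap$C, 0)
  expect_equal(ap$A, vh$a)
  expect_equal(ap$B, vh$b)
  expect_equal(predict(ap, study_temps), predict(vh, study_temps))
})

test_that("Apelblat round-trips a noiseless generator in prediction space", {
  # ln x = 495 - 30000/T - 70 ln T keeps x inside (0, 1) over the window
  x <- exp(495 - 30000 / study_temps - 70 * log(study_temps))
  f <- fit_apelblat(study_temps, x)
  expect_lt(max(abs(predict(f, study_temps) - x) / x), 1e-10)
  # the basis is linear in the parameters, so coefficients also return
  expect_equal(f$A, 495, tolerance = 1e-6)
  expect_equal(f$B, -30000, tolerance = 1e-6)
  expect_equal(f$C, -70, tolerance = 1e-6)
  expect_error(fit_apelblat(c(300, 310), c(1e-3, 2e-3)), "3 distinct")
})

test_that("Yalkowsky prediction matches the published cell and endpoint identities", {
  expect_equal(predict_yalkowsky(3.15e-2, 2.23e-5, 0.8), -2.13,
               tolerance = 2e-3)
  expect_equal(predict_yalkowsky(3.15e-2, 2.23e-5, 1), log10(3.15e-2))
  expect_equal(predict_yalkowsky(3.15e-2, 2.23e-5, 0), log10(2.23e-5))
  expect_equal(predict_yalkowsky(1e-3, 1e-3, c(0.2, 0.7)), rep(log10(1e-3), 2))
  # monotone in m1 between the endpoint log-solubilities
  preds <- predict_yalkowsky(3.15e-2, 2.23e-5, seq(0, 1, 0.1))
  expect_true(all(diff(preds) > 0))
  expect_error(predict_yalkowsky(0, 1e-3, 0.5), "\\(0, 1\\)")
})

test_that("Jouyban-Acree recovers generator coefficients at zero noise", {
  spec <- surface_spec(A1 = 18, B1 = -6400, A2 = 15, B2 = -7800,
                       j_coeffs = c(600, 200, 100), noise_cv = 0)
  g <- generate_grid(spec)
  f <- fit_jouyban_acree(g, order = 2, combined_with_vant_hoff = TRUE)
  expect_equal(unname(f$j_coeffs), c(600, 200, 100), tolerance = 1e-6)
  expect_equal(c(f$A1, f$B1, f$A2, f$B2), c(18, -6400, 15, -7800),
               tolerance = 1e-6)
  expect_lt(f$overall_rmsd_percent, 1e-6)
})

test_that("zero interaction blends give J ~ 0 and zero deviation", {
  g <- blend_grid()
  for (combined in c(FALSE, TRUE)) {
    f <- fit_jouyban_acree(g, combined_with_vant_hoff = combined)
    expect_equal(unname(f$j_coeffs), c(0, 0, 0), tolerance = 1e-6)
    expect_lt(f$overall_rmsd_percent, 1e-6)
  }
})

test_that("interaction term vanishes at the endpoints and is J0-only at m = 0.5", {
  spec <- surface_spec(noise_cv = 0)
  g <- generate_grid(spec)
  f <- fit_jouyban_acree(g, combined_with_vant_hoff = TRUE)
  # endpoints reduce to the pure van't Hoff lines, independent of J
  expect_equal(predict(f, 1, study_temps), exp(f$A1 + f$B1 / study_temps))
  expect_equal(predict(f, 0, study_temps), exp(f$A2 + f$B2 / study_temps))
  # at m = 0.5 only J0 contributes
  f0 <- f; f0$j_coeffs <- c(f$j_coeffs[1], 0, 0)
  expect_equal(predict(f, 0.5, study_temps), predict(f0, 0.5, study_temps))
})

test_that("no-intercept J estimation equals the normal-equations oracle", {
  g_small <- blend_grid(compositions = c(0, 0.3, 0.5, 0.8, 1),
                        temps = c(298.2, 308.2, 323.2))
  # perturb the mixed cells deterministically to create a nonzero excess
  mixed <- g_small$mass_fraction_cosolvent %in% c(0.3, 0.5, 0.8)
  g_small$x_exp[mixed] <- g_small$x_exp[mixed] *
    exp(0.1 * sin(seq_len(sum(mixed))))
  for (ord in 0:2) {
    f <- fit_jouyban_acree(g_small, order = ord)
    expect_equal(unname(f$j_coeffs), unname(normal_equations_j(g_small, ord)),
                 tolerance = 1e-9, label = paste("order", ord))
  }
})

test_that("Jouyban-Acree refit on its own zero-noise predictions is idempotent", {
  g <- reference_grid()
  f <- fit_jouyban_acree(g, combined_with_vant_hoff = TRUE)
  design <- expand.grid(mass_fraction_cosolvent = seq(0, 1, 0.1),
                        temperature_K = study_temps)
  pred <- predict(f, design$mass_fraction_cosolvent, design$temperature_K)
  g2 <- solubility_grid(cbind(design, x_exp = pred))
  f2 <- fit_jouyban_acree(g2, combined_with_vant_hoff = TRUE)
  expect_equal(f2$j_coeffs, f$j_coeffs, tolerance = 1e-6)
  expect_equal(c(f2$A1, f2$B1, f2$A2, f2$B2), c(f$A1, f$B1, f$A2, f$B2),
               tolerance = 1e-6)
})

test_that("Jouyban-Acree demands both endpoints and a mixed composition", {
  g <- reference_grid()
  no_pure <- solubility_grid(
    as.data.frame(g[g$mass_fraction_cosolvent < 1, ]))
  expect_error(fit_jouyban_acree(no_pure), "pure-solvent")
  endpoints_only <- solubility_grid(
    as.data.frame(g[g$mass_fraction_cosolvent %in% c(0, 1), ]))
  expect_error(fit_jouyban_acree(endpoints_only), "mixed composition")
})

test_that("all five models stay under 5 % overall RMSD on the reference grid", {
  cmp <- compare_models(reference_grid())
  expect_setequal(cmp$comparisons$model,
                  c("vanthoff", "apelblat", "yalkowsky", "jouyban_acree",
                    "jouyban_acree_vanthoff"))
  expect_true(all(cmp$comparisons$overall_rmsd_percent <= 5.0))
  # overall equals the unweighted mean of per-series values
  for (mod in cmp$comparisons$model) {
    ps <- cmp$per_series[cmp$per_series$model == mod, ]
    expect_equal(
      cmp$comparisons$overall_rmsd_percent[cmp$comparisons$model == mod],
      mean(ps$rmsd_percent))
  }
})

test_that("the generating model wins a zero-noise comparison", {
  g <- generate_grid(surface_spec(noise_cv = 0))
  cmp <- compare_models(g)
  javh <- cmp$comparisons$overall_rmsd_percent[
    cmp$comparisons$model == "jouyban_acree_vanthoff"]
  expect_lt(javh, 1e-6)
  others <- cmp$comparisons$overall_rmsd_percent[
    cmp$comparisons$model %in% c("apelblat", "yalkowsky")]
  expect_true(all(javh < others))
})

test_that("endpoint-only grids degrade gracefully in compare_models", {
  g <- reference_grid()
  endpoints_only <- solubility_grid(
    as.data.frame(g[g$mass_fraction_cosolvent %in% c(0, 1), ]))
  cmp <- compare_models(endpoints_only)
  mix_rows <- cmp$comparisons[cmp$comparisons$model %in%
                                c("yalkowsky", "jouyban_acree",
                                  "jouyban_acree_vanthoff"), ]
  expect_true(all(is.na(mix_rows$overall_rmsd_percent)))
  expect_true(all(grepl("no mixed composition", mix_rows$status)))
  temp_rows <- cmp$comparisons[cmp$comparisons$model %in%
                                 c("vanthoff", "apelblat"), ]
  expect_true(all(temp_rows$status == "ok"))
})
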