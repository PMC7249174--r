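test_that("mole_fraction matches hand-computed values", {
  mm <- bnb_molar_masses()
  # one mole of each species
  expect_equal(mole_fraction(mm$solute, mm$cosolvent), 0.5)
  expect_equal(mole_fraction(0, 1), 0)
  # 0.1 g drug in 1.0 g DMSO: n1 = 2.6924e-4 mol, n2 = 1.27995e-2 mol
  expect_equal(mole_fraction(0.1, 1.0), 0.0206, tolerance = 1e-3)
  # ternary reduces correctly when antisolvent mass is zero
  expect_equal(mole_fraction(0.1, 1.0, 0), mole_fraction(0.1, 1.0))
})

test_that("mole_fraction is scale-invariant and monotone in solute mass", {
  for (c_scale in c(0.3, 2, 117)) {
    expect_equal(mole_fraction(0.2 * c_scale, 1.5 * c_scale, 0.7 * c_scale),
                 mole_fraction(0.2, 1.5, 0.7))
  }
  masses <- seq(0.01, 1, length.out = 25)
  xs <- mole_fraction(masses, 1.0, 0.5)
  expect_true(all(diff(xs) > 0))
})

test_that("mole_fraction rejects invalid masses and constants", {
  expect_error(mole_fraction(0, 0, 0), "all masses are zero")
  expect_error(mole_fraction(-1, 1), "nonnegative")
  expect_error(mole_fraction(1, 1, molar_masses = list(
    solute = -1, cosolvent = 78, antisolvent = 18)), "positive")
})

test_that("grid validation rejects out-of-domain rows with row numbers", {
  base <- data.frame(mass_fraction_cosolvent = c(0.5, 0.5),
                     temperature_K = c(298.2, 308.2),
                     x_exp = c(1e-3, 2e-3))
  expect_s3_class(solubility_grid(base), "solubility_grid")

  bad_x <- base; bad_x$x_exp[2] <- 1.5
  expect_error(solubility_grid(bad_x), "x_exp.*row\\(s\\) 2")
  bad_x$x_exp[2] <- 0
  expect_error(solubility_grid(bad_x), "x_exp")

  dup <- rbind(base, base[1, ])
  expect_error(solubility_grid(dup), "duplicate.*row\\(s\\) 3")

  missing_col <- base[, -3]
  expect_error(solubility_grid(missing_col), "missing required column")

  bad_t <- base; bad_t$temperature_K[1] <- -5
  expect_error(solubility_grid(bad_t), "temperature")
})

test_that("write_grid / read_grid round-trips grids exactly", {
  g <- reference_grid()
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid(g, path)
  g2 <- read_grid(path)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_identical(attr(g2, "solute"), attr(g, "solute"))
  expect_identical(attr(g2, "provenance"), attr(g, "provenance"))
  expect_equal(attr(g2, "pressure_MPa"), attr(g, "pressure_MPa"))

  # sd absent round-trips to NA
  g3 <- solubility_grid(data.frame(mass_fraction_cosolvent = 0.5,
                                   temperature_K = c(300, 310),
                                   x_exp = c(1e-3, 2e-3)))
  path3 <- withr::local_tempfile(fileext = ".csv")
  write_grid(g3, path3)
  expect_true(all(is.na(read_grid(path3)$sd)))
})

test_that("reference dataset has the published shape and key cells", {
  g <- reference_grid()
  expect_equal(nrow(g), 55)
  expect_equal(length(unique(g$mass_fraction_cosolvent)), 11)
  expect_equal(length(unique(g$temperature_K)), 5)
  cell <- function(m, t) g$x_exp[g$mass_fraction_cosolvent == m &
                                   g$temperature_K == t]
  expect_equal(cell(0.0, 298.2), 2.23e-5)
  expect_equal(cell(1.0, 323.2), 1.69e-1)
  expect_equal(cell(0.8, 298.2), 7.42e-3)
})

test_that("the power-of-ten cell correction is applied and recorded", {
  g <- reference_grid(corrected = TRUE)
  cell <- g$x_exp[g$mass_fraction_cosolvent == 0.2 & g$temperature_K == 323.2]
  expect_equal(cell, 7.05e-4)
  expect_true(any(grepl("power-of-ten", attr(g, "provenance"))))

  raw <- reference_grid(corrected = FALSE)
  cell_raw <- raw$x_exp[raw$mass_fraction_cosolvent == 0.2 &
                          raw$temperature_K == 323.2]
  expect_equal(cell_raw, 7.05e-5)
  expect_false(any(grepl("power-of-ten", attr(raw, "provenance"))))
})

test_that("corrected reference solubilities increase with temperature in every series", {
  g <- reference_grid()
  for (m in unique(g$mass_fraction_cosolvent)) {
    s <- g[g$mass_fraction_cosolvent == m, ]
    s <- s[order(s$temperature_K), ]
    expect_true(all(diff(s$x_exp) > 0), label = paste("series m =", m))
  }
  # pre-correction, exactly one series breaks monotonicity
  raw <- reference_grid(corrected = FALSE)
  broken <- vapply(unique(raw$mass_fraction_cosolvent), function(m) {
    s <- raw[raw$mass_fraction_cosolvent == m, ]
    any(diff(s$x_exp[order(s$temperature_K)]) <= 0)
  }, logical(1))
  expect_equal(sum(broken), 1)
})
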