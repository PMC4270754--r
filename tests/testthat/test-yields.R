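# Radiolysis yields: quartic ln(LET) model, ferric combination, unit
# conversion, LET-energy fitting and spectrum weighting.

coeffs <- default_constants()$radiolysis_coefficients

test_that("packaged coefficient table expands the printed column scales", {
  # printed scales: alpha1..alpha3 are x1e-2, alpha4 is x1e-3
  expect_equal(coeffs$H$alpha, c(3.601, -0.1353, -0.05974, -0.01929, -0.004979))
  expect_equal(coeffs$OH$alpha, c(2.766, -0.1880, -0.08239, -0.02127, -0.004637))
  expect_equal(coeffs$H2O2$alpha, c(0.8438, 0.05682, 0.02169, 0.006284, 0.001988))
})

test_that("primary yields reduce to the constant term at LET = 1 and match hand-evaluated values at 1.28", {
  for (sp in names(coeffs)) {
    expect_identical(primary_yield(sp, 1.0, coeffs[[sp]]), coeffs[[sp]]$alpha[1])
  }
  # frozen from an independent hand evaluation of the quartic at ln(1.28)
  expect_equal(primary_yield("H", 1.28, coeffs$H), 3.5636506, tolerance = 1e-7)
  expect_equal(primary_yield("OH", 1.28, coeffs$OH), 2.7142323, tolerance = 1e-7)
  expect_equal(primary_yield("H2O2", 1.28, coeffs$H2O2), 0.8592503, tolerance = 1e-7)
})

test_that("primary_yield validates LET and the species/coefficient pairing", {
  expect_error(primary_yield("H", 0, coeffs$H), "positive")
  expect_error(primary_yield("H", -1, coeffs$H), "positive")
  expect_error(primary_yield("OH", 1.28, coeffs$H), "mismatch")
  expect_warning(primary_yield("H", 0.05, coeffs$H), "outside the supported range")
  expect_warning(primary_yield("H", 50, coeffs$H), "outside the supported range")
})

test_that("ferric yield reproduces the published Ir-192 values and the LET = 1 closed form", {
  expect_equal(ferric_yield(1.28), 15.123, tolerance = 1e-3)
  expect_equal(ferric_yield(1.237), 15.144, tolerance = 1e-3)
  # full-precision frozen values from the same independent evaluation
  expect_equal(ferric_yield(1.28), 15.1236847, tolerance = 1e-7)
  expect_equal(ferric_yield(1.237), 15.1439095, tolerance = 1e-7)
  # at LET = 1 only the constant terms survive
  expect_equal(ferric_yield(1.0), 3 * 3.601 + 2.766 + 2 * 0.8438)
  expect_error(ferric_yield(1.28, coeffs[c("H", "OH")]), "exactly")
})

test_that("ferric yield decreases strictly with LET over the photon range", {
  grid <- seq(0.5, 5, by = 0.1)
  g <- vapply(grid, ferric_yield, numeric(1))
  expect_true(all(diff(g) < 0))
})

test_that("unit conversion matches the published mol/J values and inverts exactly", {
  # agreement within one unit of the last published digit (1e-9 mol/J)
  expect_equal(to_mol_per_joule(15.123), 1.567e-6, tolerance = 1e-9 / 1.567e-6)
  expect_equal(to_mol_per_joule(15.144), 1.569e-6, tolerance = 1e-9 / 1.569e-6)
  expect_identical(to_mol_per_joule(0), 0)
  expect_error(to_mol_per_joule(-1), "non-negative")
  g <- c(0.1, 1, 15.123, 400)
  expect_equal(from_mol_per_joule(to_mol_per_joule(g)), g, tolerance = 1e-12)
})

test_that("the two G-determination routes agree within 1 percent", {
  weighted <- default_constants()$fricke$g_value_mol_per_J
  from_let <- to_mol_per_joule(ferric_yield(default_constants()$let_ir192$linear_fit_keV_per_um))
  expect_lt(abs(from_let - weighted) / weighted, 0.01)
})

test_that("LET-energy fits interpolate exactly with degree+1 anchors", {
  line <- fit_let_curve(data.frame(energy = c(1, 3), let = c(2, 4)), degree = 1)
  expect_equal(interpolate_let(line, 2), 3.0, tolerance = 1e-10)
  expect_equal(unname(stats::residuals(line$fit)), c(0, 0), tolerance = 1e-12)

  # three non-collinear anchors; expected coefficients from solving the
  # 3x3 Vandermonde system independently of lm()
  anc <- data.frame(energy = c(0.08, 0.6, 1.25), let = c(3.2, 1.7, 1.25))
  V <- outer(anc$energy, 0:2, `^`)
  beta <- solve(V, anc$let)
  quad <- fit_let_curve(anc, degree = 2)
  expect_equal(unname(stats::coef(quad$fit)), beta, tolerance = 1e-8)
  for (i in seq_len(nrow(anc))) {
    expect_equal(interpolate_let(quad, anc$energy[i]), anc$let[i],
                 tolerance = 1e-8)
  }
})

test_that("a quadratic fit to collinear anchors degenerates to the line", {
  anc <- data.frame(energy = c(0.1, 0.5, 1.0), let = 5 - 2 * c(0.1, 0.5, 1.0))
  quad <- fit_let_curve(anc, degree = 2)
  expect_equal(unname(stats::coef(quad$fit))[3], 0, tolerance = 1e-8)
  expect_equal(interpolate_let(quad, 0.75), 5 - 2 * 0.75, tolerance = 1e-8)
})

test_that("a constant-LET anchor set predicts that LET everywhere in range", {
  anc <- data.frame(energy = c(0.2, 0.8), let = c(1.5, 1.5))
  fit <- fit_let_curve(anc, degree = 1)
  expect_equal(interpolate_let(fit, 0.37), 1.5, tolerance = 1e-10)
})

test_that("LET-curve fitting validates its inputs and flags extrapolation", {
  expect_error(fit_let_curve(data.frame(energy = 1, let = 2), degree = 1), "at least")
  expect_error(fit_let_curve(data.frame(energy = c(1, 1), let = c(2, 3)), 1),
               "distinct")
  line <- fit_let_curve(data.frame(energy = c(1, 3), let = c(2, 4)), 1)
  expect_warning(interpolate_let(line, 5), "extrapolating")
  falling <- fit_let_curve(data.frame(energy = c(1, 2), let = c(2, 1)), 1)
  expect_warning(expect_error(interpolate_let(falling, 10), "non-positive"))
})

test_that("spectrum-weighted G value reduces to known means", {
  gt <- data.frame(energy = c(0.1, 0.2), g = c(1.5e-6, 1.6e-6))
  uni <- weighted_g_value(gt, data.frame(energy = gt$energy, weight = c(1, 1)))
  expect_equal(uni$value, 1.55e-6)
  expect_identical(uni$method, "energy_weighted")
  point <- weighted_g_value(gt, data.frame(energy = 0.2, weight = 7))
  expect_equal(point$value, 1.6e-6)
  wm <- weighted_g_value(gt, data.frame(energy = gt$energy, weight = c(1, 3)))
  expect_equal(wm$value, 1.575e-6)  # hand-computed weighted mean
})

test_that("spectrum weighting validates tables, weights and bin matching", {
  gt <- data.frame(energy = c(0.1, 0.2), g = c(1.5e-6, 1.6e-6))
  expect_error(weighted_g_value(gt, data.frame(energy = 0.1, weight = 0)),
               "positive")
  expect_error(weighted_g_value(gt, data.frame(energy = 0.1, weight = -1)),
               "non-negative")
  expect_error(weighted_g_value(gt[0, ], data.frame(energy = 0.1, weight = 1)),
               "non-empty")
  # nearest-bin matching: 0.11 maps to the 0.1 bin, 0.5 is out of tolerance
  near <- weighted_g_value(gt, data.frame(energy = 0.11, weight = 1))
  expect_equal(near$value, 1.5e-6)
  expect_error(weighted_g_value(gt, data.frame(energy = 0.5, weight = 1)),
               "no G-table bin")
})

test_that("energy-table CSV reader round-trips anchors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("energy_MeV,let", "0.08,3.2", "0.662,1.7", "1.25,1.2"), f)
  df <- read_energy_table(f, "let")
  expect_equal(df$energy, c(0.08, 0.662, 1.25))
  expect_equal(df$let, c(3.2, 1.7, 1.2))
  unlink(f)
})
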