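test_that("calibration fitting recovers exact and noisy lines", {
  # identity line
  cal <- fitCalibration(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(cal@slope, 1)
  expect_equal(cal@intercept, 0)
  expect_equal(cal@rSquared, 1)
  # two-point exact
  cal2 <- fitCalibration(c(0.1, 0.5), c(0.2, 1.0))
  expect_equal(cal2@slope, 2)
  expect_equal(cal2@intercept, 0, tolerance = 1e-12)
  # noisy seven-point table: recovered slope within 1% of the generating 1.8
  set.seed(7)
  conc <- seq(0.10, 0.50, length.out = 7)
  abs_ <- 1.8 * conc + 0.01 + rnorm(7, sd = 1e-2 * 1e-1)
  # oracle: closed-form OLS on the generated table
  sxx <- sum((conc - mean(conc))^2)
  slope_ols <- sum((conc - mean(conc)) * (abs_ - mean(abs_))) / sxx
  cal3 <- fitCalibration(conc, abs_)
  expect_equal(cal3@slope, slope_ols, tolerance = 1e-12)
  expect_lt(abs(cal3@slope - 1.8) / 1.8, 0.01)
  # degenerate design errors
  expect_error(fitCalibration(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3)),
               "unusable")
})

test_that("absorbance inversion converts to mol/L and clamps negatives", {
  cal <- new("CalibrationCurve", concentrations = c(0.1, 0.5),
             absorbances = c(0.1, 0.5), slope = 1, intercept = 0,
             rSquared = 1)
  expect_equal(absorbanceToConcentration(cal, 0.25), 2.5e-4)
  cal2 <- new("CalibrationCurve", concentrations = c(0.1, 0.5),
              absorbances = c(0.3, 1.1), slope = 2, intercept = 0.1,
              rSquared = 1)
  expect_equal(absorbanceToConcentration(cal2, 0.1), 0)      # at intercept
  expect_warning(absorbanceToConcentration(cal2, 0.05), "clamped")
  cal3 <- new("CalibrationCurve", concentrations = c(0.1, 0.5),
              absorbances = c(0.19, 0.91), slope = 1.8, intercept = 0.01,
              rSquared = 1)
  expect_equal(absorbanceToConcentration(cal3, 0.46), 2.5e-4)
  cal0 <- cal; cal0@slope <- 0
  expect_error(absorbanceToConcentration(cal0, 0.2), "zero")
})

test_that("adsorption capacity follows C_s V_s M / m_p with SI units", {
  e0 <- bindingExperiment(2.4e-5, 0.1, 0.003, 0, polymerMass = 0.15)
  expect_equal(adsorptionCapacity(e0), 0)
  e <- bindingExperiment(2.4e-5, 0.1, 0.003, 8e-5, polymerMass = 0.15)
  expect_equal(adsorptionCapacity(e), 8e-5 * 0.003 * 314.46 / 0.15 * 1e3,
               tolerance = 1e-12)
  expect_equal(adsorptionCapacity(e), 0.5031, tolerance = 1e-3)
  # scaling laws: doubling m_p halves Q; Q linear in C_s and V_s
  set.seed(11)
  for (i in 1:10) {
    cs <- runif(1, 1e-6, 2e-4); vs <- runif(1, 1e-3, 1e-2)
    mp <- runif(1, 0.05, 0.5); sc <- runif(1, 0.5, 3)
    q1 <- adsorptionCapacity(bindingExperiment(1e-3, 1, vs, cs,
                                               polymerMass = mp))
    q2 <- adsorptionCapacity(bindingExperiment(1e-3, 1, vs, cs,
                                               polymerMass = 2 * mp))
    expect_equal(q2, q1 / 2, tolerance = 1e-12)
    q3 <- adsorptionCapacity(bindingExperiment(1e-3, 1, vs, sc * cs,
                                               polymerMass = mp))
    expect_equal(q3, sc * q1, tolerance = 1e-12)
  }
})

test_that("imprinting and enrichment factors are ratios with guards", {
  expect_equal(imprintingFactor(2.2, 2.2), 1)
  expect_equal(imprintingFactor(3.61, 1.31), 2.756, tolerance = 1e-3)
  expect_equal(imprintingFactor(1.65, 0.446), 3.7, tolerance = 1e-2)
  # scale invariance
  expect_equal(imprintingFactor(3 * 1.65, 3 * 0.446),
               imprintingFactor(1.65, 0.446))
  expect_error(imprintingFactor(1, 0), "undefined")
  expect_equal(enrichmentFactor(2.4e-5, 2.4e-5), 1)
  expect_equal(enrichmentFactor(2.472e-4, 2.4e-5), 10.3)
  # mass-balance ceiling: full uptake of a 100 mL bath eluted into 3 mL
  expect_equal(enrichmentFactor(2.4e-5 * 0.1 / 0.003, 2.4e-5), 100 / 3)
  expect_error(enrichmentFactor(1e-5, 0), "> 0")
})

test_that("mass balance violations are flagged and replicates summarized", {
  expect_warning(
    bindingExperiment(2.4e-5, 0.1, 0.003, 1e-2, polymerMass = 0.15),
    "mass balance")
  e <- bindingExperiment(2.4e-5, 0.1, 0.003, c(7.9e-5, 8.0e-5, 8.1e-5),
                         polymerMass = 0.15)
  br <- bindingResult(e)
  expect_equal(br$n, 3L)
  expect_equal(br$qMean, mean(br$q))
  expect_equal(br$qSd, sd(br$q))   # sample sd, n-1 denominator
  expect_true(br$massBalanceOk)
})

test_that("round trip: calibration table -> fit -> inversion recovers input", {
  tab <- genCalibration(slope = 1.8, intercept = 0.01, noiseSd = 1e-4,
                        seed = 5)
  cal <- fitCalibration(tab$concentration_mmol_per_L, tab$absorbance)
  back <- absorbanceToConcentration(cal, tab$absorbance) * 1e3  # mmol/L
  expect_equal(back, tab$concentration_mmol_per_L, tolerance = 5e-3)
})

test_that("calibration and binding file readers round-trip", {
  tf <- tempfile(fileext = ".csv")
  write.csv(genCalibration(noiseSd = 0, seed = 1), tf, row.names = FALSE)
  cal <- readCalibrationCsv(tf)
  expect_equal(cal@slope, 1.8, tolerance = 1e-9)
  expect_equal(length(cal@concentrations), 7L)
  tj <- tempfile(fileext = ".json")
  jsonlite::write_json(list(c_incubation_mol_per_L = 2.4e-5,
                            v_incubation_L = 0.1, v_elution_L = 0.003,
                            c_elution_mol_per_L = c(8e-5, 8.2e-5),
                            molar_mass_g_per_mol = 314.46,
                            polymer_mass_g = 0.15), tj, auto_unbox = TRUE,
                       digits = NA)
  e <- readBindingJson(tj)
  expect_s4_class(e, "BindingExperiment")
  expect_equal(length(e@cElution), 2L)
})
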