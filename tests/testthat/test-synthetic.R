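test_that("generators are pure functions of (seed, name)", {
  a <- genUptake("PSO", list(qE = 3.61, k2 = 0.0049), noiseSd = 0.1,
                 seed = 1)
  b <- genUptake("PSO", list(qE = 3.61, k2 = 0.0049), noiseSd = 0.1,
                 seed = 1)
  expect_identical(a@qT, b@qT)
  expect_false(identical(
    a@qT, genUptake("PSO", list(qE = 3.61, k2 = 0.0049), noiseSd = 0.1,
                    seed = 2)@qT))
  i1 <- genIntrusion(44, 0.5, 0.609, noiseFrac = 0.01, seed = 3)
  i2 <- genIntrusion(44, 0.5, 0.609, noiseFrac = 0.01, seed = 3)
  expect_identical(i1@cumulativeVolume, i2@cumulativeVolume)
  v1 <- genVolume(shape = c(16L, 16L, 16L), seed = 4)
  v2 <- genVolume(shape = c(16L, 16L, 16L), seed = 4)
  expect_identical(voxelData(v1$truth), voxelData(v2$truth))
  expect_identical(voxelData(v1$stack), voxelData(v2$stack))
  d1 <- genDsc(140.3, noiseSd = 0.01, seed = 5)
  d2 <- genDsc(140.3, noiseSd = 0.01, seed = 5)
  expect_identical(d1@revHeatFlow, d2@revHeatFlow)
  c1 <- genIndentation(93, noiseFrac = 0.01, seed = 6)
  c2 <- genIndentation(93, noiseFrac = 0.01, seed = 6)
  expect_identical(c1@load, c2@load)
})

test_that("noiseless uptake equals the exact model curve", {
  times <- c(15, 30, 60, 240, 1260)
  s <- genUptake("PSO", list(qE = 3.61, k2 = 0.0049), noiseSd = 0, seed = 1)
  expect_equal(s@qT, psoModel(times, 3.61, 0.0049))
  s2 <- genUptake("PFO", list(qE = 2, k1 = 0.01), noiseSd = 0, seed = 1)
  expect_equal(s2@qT, pfoModel(times, 2, 0.01))
  s3 <- genUptake("crank", list(d = 3.9e-13, l = 190e-6, alpha = 0.4402),
                  noiseSd = 0, seed = 1)
  expect_equal(s3@qT,
               crankUptakeFraction(times * 60, 3.9e-13, 190e-6, 0.4402,
                                   crankRoots(0.4402, 6)))
})

test_that("generator outputs satisfy the consuming modules' invariants", {
  s <- genUptake("PSO", list(qE = 3.61, k2 = 0.0049), noiseSd = 0.3,
                 seed = 7)
  expect_s4_class(s, "UptakeSeries")           # validity enforces them
  expect_true(all(s@qT >= 0))
  cur <- genIntrusion(44, 0.5, 0.609, noiseFrac = 0.05, seed = 7)
  expect_s4_class(cur, "IntrusionCurve")
  expect_true(all(diff(cur@cumulativeVolume) >= 0))
  v <- genVolume(shape = c(16L, 16L, 16L), seed = 7)
  expect_s4_class(v$stack, "GrayscaleStack")
  expect_s4_class(v$truth, "VoxelVolume")
  ic <- genIndentation(93, noiseFrac = 0.02, seed = 7)
  expect_s4_class(ic, "IndentationCurve")
  un <- ic@load[ic@segment == "unloading"]
  expect_true(all(diff(un) < 0))
  expect_s4_class(genDsc(140.3, noiseSd = 0.01, seed = 7), "DscTrace")
  tab <- genCalibration(seed = 7)
  expect_equal(nrow(tab), 7L)                  # seven-point calibration
  expect_equal(range(tab$concentration_mmol_per_L), c(0.10, 0.50))
})

test_that("GRF volumes hit the target porosity by quantile construction", {
  for (tp in c(30, 46, 50, 70)) {
    v <- genVolume(shape = c(32L, 32L, 32L), targetPorosity = tp, seed = 9)
    expect_equal(porosityFraction(v$truth), tp, tolerance = 0.01)
  }
  expect_error(genVolume(targetPorosity = 0), "porosity")
  expect_error(genVolume(targetPorosity = 100), "porosity")
})

test_that("round trips: noiseless generation then analysis recovers inputs", {
  # intrusion -> inversion
  psd <- invertIntrusion(genIntrusion(44, 0.5, 0.609, noiseFrac = 0,
                                      seed = 1))
  expect_equal(medianDiameter(psd), 44, tolerance = 0.02 * 44)
  # sigma -> 0 degenerates toward a single step
  psd2 <- invertIntrusion(genIntrusion(44, 1e-4, 0.6, noiseFrac = 0,
                                       seed = 1))
  expect_equal(medianDiameter(psd2), 44, tolerance = 0.02 * 44)
  expect_equal(modalDiameter(psd2), 44, tolerance = 0.05 * 44)
  # crank uptake -> diffusion fit, 3 significant figures
  s <- genUptake("crank", list(d = 3.9e-13, l = 190e-6, alpha = 0.4402),
                 noiseSd = 0, seed = 1)
  f <- fitDiffusion(s, l = 190e-6, alpha = 0.4402, qInf = 1)
  expect_lt(abs(dApparent(f) - 3.9e-13) / 3.9e-13, 1e-3)
  # indentation -> Oliver-Pharr
  expect_equal(oliverPharr(genIndentation(93))@sampleModulus, 93,
               tolerance = 0.005 * 93)
  # DSC -> Tg (sharp transition, flat baselines: exact)
  expect_equal(tgMidpoint(genDsc(140.3, transitionWidth = 5,
                                 baselineSlopes = c(0, 0)))$tg,
               140.3, tolerance = 0.02)
  # calibration -> OLS
  tab <- genCalibration(noiseSd = 0, seed = 1)
  cal <- fitCalibration(tab$concentration_mmol_per_L, tab$absorbance)
  expect_equal(cal@slope, 1.8, tolerance = 1e-9)
  expect_equal(cal@intercept, 0.01, tolerance = 1e-9)
})
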