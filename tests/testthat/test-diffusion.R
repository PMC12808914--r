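test_that("alpha follows the bath/polymer mass balance", {
  # half the analyte bound -> alpha = 1
  expect_equal(computeAlpha(1e-3, 1, 100, qInf = 50, mP = 1), 1)
  # all analyte bound -> alpha = 0
  expect_equal(computeAlpha(1e-3, 1, 100, qInf = 100, mP = 1), 0)
  # the batch study's bath (0.0024 mmol in 100 mL, CBD) with a bound mass
  # of 0.524 mg gives the alpha used throughout the diffusion analysis
  a <- computeAlpha(2.4e-5, 0.1, 314.46, qInf = 0.524, mP = 1)
  expect_equal(a, (0.755 - 0.524) / 0.524, tolerance = 2e-3)
  expect_equal(a, 0.4402, tolerance = 2e-3)
  expect_error(computeAlpha(1e-3, 1, 100, qInf = 200, mP = 1),
               "mass balance")
})

test_that("series roots solve tan(q) = -alpha q in the stated brackets", {
  for (alpha in c(0.1, 0.4402, 5)) {
    r <- crankRoots(alpha, 6)
    expect_true(all(diff(r) > 0))
    for (n in 1:6) {
      expect_gt(r[n], (2 * n - 1) * pi / 2)
      expect_lt(r[n], n * pi)
      expect_lt(abs(tan(r[n]) + alpha * r[n]), 1e-9)
    }
  }
  # bracketing limits: q_n -> (2n-1)pi/2 as alpha -> Inf, -> n*pi as -> 0
  big <- crankRoots(1e5, 3); small <- crankRoots(1e-5, 3)
  expect_equal(big, (2 * (1:3) - 1) * pi / 2, tolerance = 1e-3)
  expect_equal(small, (1:3) * pi, tolerance = 1e-3)
})

test_that("roots agree with a brute-force sign-scan oracle to 4 decimals", {
  r <- crankRoots(0.4402, 6)
  expect_equal(r, bruteCrankRoots(0.4402, 6), tolerance = 1e-4)
})

test_that("prefactor series normalizes to 1 for any alpha", {
  for (alpha in c(0.1, 0.4402, 5)) {
    roots <- crankRoots(alpha, 5000)
    pref <- 2 * alpha * (1 + alpha) / (1 + alpha + alpha^2 * roots^2)
    expect_equal(sum(pref), 1, tolerance = 2e-3)
  }
})

test_that("fractional uptake behaves like a finite-bath diffusion solution", {
  alpha <- 0.4402; l <- 190e-6
  roots6 <- crankRoots(alpha, 6)
  # asymptote and t = 0 truncation residue of the six-term sum
  expect_equal(crankUptakeFraction(1e9, 3.9e-13, l, alpha, roots6), 1)
  pref6 <- 2 * alpha * (1 + alpha) / (1 + alpha + alpha^2 * roots6^2)
  expect_equal(crankUptakeFraction(0, 3.9e-13, l, alpha, roots6),
               1 - sum(pref6))
  expect_equal(crankUptakeFraction(0, 3.9e-13, l, alpha, roots6), 0.109,
               tolerance = 1e-2)
  expect_equal(crankUptakeFraction(0, 3.9e-13, l, alpha,
                                   crankRoots(alpha, 2000)), 0,
               tolerance = 5e-3)
  # six terms agree with a 1000-term evaluation at 1 h within truncation
  f6 <- crankUptakeFraction(3600, 3.9e-13, l, alpha, roots6)
  f1000 <- crankUptakeFraction(3600, 3.9e-13, l, alpha,
                               crankRoots(alpha, 1000))
  expect_equal(f6, f1000, tolerance = 1e-3)
  # monotone in t and in D
  ts <- seq(0, 80000, length.out = 60)
  expect_true(all(diff(crankUptakeFraction(ts, 3.9e-13, l, alpha,
                                           roots6)) > 0))
  ds <- seq(1e-13, 8e-13, length.out = 30)
  v <- vapply(ds, function(d)
    crankUptakeFraction(3600, d, l, alpha, roots6), numeric(1))
  expect_true(all(diff(v) > 0))
  expect_error(crankUptakeFraction(100, 1e-13, l, alpha, numeric(0)),
               "empty")
})

test_that("diffusion fitting recovers the generating coefficient", {
  alpha <- 0.4402; l <- 190e-6
  for (dtrue in c(3.9e-13, 2.5e-13)) {
    s <- genUptake("crank", list(d = dtrue, l = l, alpha = alpha),
                   noiseSd = 0, seed = 1)
    f <- fitDiffusion(s, l = l, alpha = alpha, qInf = 1)
    expect_equal(dApparent(f), dtrue, tolerance = 1e-3)
  }
  # imprinted/nonimprinted transport ratio recovered near 1.6
  ratio <- 3.9e-13 / 2.5e-13
  fm <- fitDiffusion(genUptake("crank", list(d = 3.9e-13, l = l,
                                             alpha = alpha), seed = 1),
                     l = l, alpha = alpha, qInf = 1)
  fn <- fitDiffusion(genUptake("crank", list(d = 2.5e-13, l = l,
                                             alpha = alpha), seed = 1),
                     l = l, alpha = alpha, qInf = 1)
  expect_equal(dApparent(fm) / dApparent(fn), ratio, tolerance = 1e-3)
  expect_equal(dApparent(fm) / dApparent(fn), 1.6, tolerance = 0.05)
  # zero equilibrium proxy errors
  s0 <- uptakeSeries(c(15, 1260), c(0, 0))
  expect_error(fitDiffusion(s0, l = l, alpha = alpha), "zero")
})

test_that("late-time proxy normalization matches explicit q_inf closely", {
  alpha <- 0.4402; l <- 190e-6
  s <- genUptake("crank", list(d = 3.9e-13, l = l, alpha = alpha,
                               qInf = 3.5), seed = 1)
  f <- fitDiffusion(s, l = l, alpha = alpha)   # proxy: Q at 1260 min
  expect_equal(f@qInf, s@qT[length(s@qT)])
  expect_equal(dApparent(f), 3.9e-13, tolerance = 0.1)
})
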