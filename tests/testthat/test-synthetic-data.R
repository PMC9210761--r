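# ground-truth two-state systems and simulated measurements

test_that("two-state construction orders the reference states correctly", {
  sys <- getTwoState()
  ext <- sys@states$extended
  cmp <- sys@states$compact
  expect_lt(rgyr(cmp), rgyr(ext))                       # strict by construction

  # extended dmax close to domains + linker contour
  lay <- flexsaxs:::topologyLayout(sys@topology)
  extents <- vapply(which(lay$segType == "domain"), function(si)
    conformationMetrics(lay$segObj[[si]]@beads)[["dmax"]], numeric(1))
  contour <- sum(vapply(which(lay$segType == "linker"), function(si)
    (lay$segN[si] + 1) * lay$segObj[[si]]@bondLength, numeric(1)))
  bound <- sum(extents) + contour
  expect_lt(abs(maxDim(ext) / bound - 1), 0.15)

  # determinism and seed sensitivity
  sysB <- makeTwoStateSystem(nDomains = 2, linkerLengths = 19L, seed = 42)
  expect_identical(sysB@states$compact@coords, cmp@coords)
  expect_identical(sysB@states$extended@coords, ext@coords)

  expect_error(makeTwoStateSystem(nDomains = 1), "at least 2")
  expect_error(makeTwoStateSystem(nDomains = 3, linkerLengths = 19), "entries")
})

test_that("simulated curves follow the declared noise model", {
  sys <- getTwoState()
  q <- defaultQGrid()

  noiseless <- makeTwoStateSystem(nDomains = 2, linkerLengths = 19L, seed = 42,
                                  noiseFrac = 0)
  cv0 <- simulateCurve(noiseless, q, seed = 5)
  expect_equal(intensities(cv0), trueProfile(noiseless, q), tolerance = 1e-12)

  # standardized residuals over 1e4 points: mean ~ 0, variance ~ 1
  qq <- defaultQGrid(10000)
  cvn <- simulateCurve(sys, qq, seed = 7)
  z <- (intensities(cvn) - trueProfile(sys, qq)) / sigmas(cvn)
  expect_lt(abs(mean(z)), 0.03)
  expect_gt(var(z), 0.95)
  expect_lt(var(z), 1.05)

  # error model: sigma = noiseFrac * I * (1 + q/qHalf)
  It <- trueProfile(sys, q)
  expect_equal(sigmas(simulateCurve(sys, q, seed = 1)),
               0.01 * It * (1 + q / 0.2), tolerance = 1e-12)

  # same seed -> identical simulated curve
  expect_identical(intensities(simulateCurve(sys, q, seed = 3)),
                   intensities(simulateCurve(sys, q, seed = 3)))
})

test_that("the true mixture profile is chi2-consistent with its simulations", {
  sys <- getTwoState()
  q <- defaultQGrid()
  It <- trueProfile(sys, q)
  ch <- vapply(1:50, function(s) chi2Fit(It, simulateCurve(sys, q, seed = s))@chi2,
               numeric(1))
  expect_gt(mean(ch), 0.9)
  expect_lt(mean(ch), 1.1)
})

test_that("recovery experiment identifies planted states end to end", {
  sys <- getTwoState()
  rep1 <- recoveryExperiment(sys, poolSize = 400, seed = 3)
  expect_true(rep1$recoveredPair)
  expect_equal(rep1$weights, c(0.5, 0.5))
  expect_lte(rep1$chi2Ensemble, rep1$chi2Single)
  expect_lte(rep1$chi2Pair, rep1$chi2Single)
  expect_lt(max(abs(sort(rep1$rgRecovered) / sort(unname(rep1$rgTrue)) - 1)), 0.05)

  # zero-noise, no decoys beyond the planted pair at minimum pool size:
  noiseless <- makeTwoStateSystem(nDomains = 2, linkerLengths = 19L, seed = 42,
                                  noiseFrac = 0)
  rep0 <- recoveryExperiment(noiseless, poolSize = 12, seed = 4)
  expect_true(setequal(rep0$members, 1:2))
  # residual chi2 reflects only the histogram-vs-direct profile difference
  # against the near-zero placeholder errors
  expect_lt(rep0$chi2Ensemble, 0.05)
})

test_that("more noise never helps recovery", {
  rate <- vapply(c(0.01, 0.05, 0.10), function(nf) {
    sys <- makeTwoStateSystem(nDomains = 2, linkerLengths = 19L, seed = 42,
                              noiseFrac = nf)
    mean(vapply(1:6, function(s)
      recoveryExperiment(sys, poolSize = 300, seed = s)$recoveredPair,
      logical(1)))
  }, numeric(1))
  expect_true(rate[3] <= rate[1])
})
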