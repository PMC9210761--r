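# chi-square fitting with scale/offset and minimal-ensemble selection

test_that("chi2 fit closes exactly on identity and affine cases", {
  q <- seq(0.01, 0.5, length.out = 60)
  m <- 10 * exp(-q^2 * 500) + 0.5
  idem <- chi2Fit(m, ScatteringCurve(q, m, rep(0.2, 60)))
  expect_equal(idem@a, 1)
  expect_equal(idem@b, 0, tolerance = 1e-12)
  expect_equal(idem@chi2, 0, tolerance = 1e-20)

  aff <- chi2Fit(m, ScatteringCurve(q, 2 * m + 5, runif(60, 0.1, 0.5)))
  expect_equal(aff@a, 2, tolerance = 1e-10)
  expect_equal(aff@b, 5, tolerance = 1e-10)
  expect_equal(aff@chi2, 0, tolerance = 1e-15)
})

test_that("closed-form (a, b, chi2) equals a refined grid-search oracle", {
  set.seed(4)
  q <- seq(0.01, 0.5, length.out = 50)
  m <- runif(50, 1, 10)
  cv <- ScatteringCurve(q, 2.5 * m + 1.2 + rnorm(50, 0, 0.3), runif(50, 0.2, 0.5))
  f <- chi2Fit(m, cv)
  # two-stage dense grid zooming onto the optimum
  w <- 1 / sigmas(cv)^2
  obj <- function(a, b) sum(w * (a * m + b - intensities(cv))^2) / 50
  ctr <- c(2.5, 1.2); span <- c(0.5, 0.5)
  for (stage in 1:6) {
    gr <- expand.grid(a = seq(ctr[1] - span[1], ctr[1] + span[1], length.out = 81),
                      b = seq(ctr[2] - span[2], ctr[2] + span[2], length.out = 81))
    v <- mapply(obj, gr$a, gr$b)
    ctr <- c(gr$a[which.min(v)], gr$b[which.min(v)])
    span <- span / 10
  }
  expect_lt(abs(f@a / ctr[1] - 1), 1e-6)
  expect_lt(abs(f@b / ctr[2] - 1), 1e-6)
  expect_lte(f@chi2, min(v) * (1 + 1e-9))
  # independent weighted-lm oracle
  o <- lmChi2(m, cv)
  expect_equal(f@a, o$a, tolerance = 1e-9)
  expect_equal(f@b, o$b, tolerance = 1e-9)
  expect_equal(f@chi2, o$chi2, tolerance = 1e-9)
})

test_that("chi2 fit contracts: short curves, degenerate designs, scaling invariance", {
  expect_error(chi2Fit(c(1, 2), ScatteringCurve(c(0.1, 0.2), c(1, 2), c(0.1, 0.1))),
               "at least 3")
  m10 <- seq(10, 1, length.out = 10)
  cv <- ScatteringCurve(seq(0.1, 0.5, length.out = 10), 30 - 2 * m10, rep(0.1, 10))
  expect_error(chi2Fit(rep(2, 10), cv), "degenerate")
  expect_warning(chi2Fit(m10, cv), "a <= 0")

  set.seed(6)
  m <- runif(20, 1, 5)
  cv1 <- ScatteringCurve(seq(0.1, 0.5, length.out = 20), 3 * m + rnorm(20, 0, 0.2),
                         runif(20, 0.1, 0.3))
  cv2 <- ScatteringCurve(qValues(cv1), 4 * intensities(cv1), 4 * sigmas(cv1))
  expect_equal(chi2Fit(m, cv1)@chi2, chi2Fit(m, cv2)@chi2, tolerance = 1e-12)
})

test_that("profile interpolation is linear and refuses extrapolation", {
  qm <- seq(0.01, 0.5, length.out = 20)
  I <- 2 * qm + 1
  expect_equal(interpolateProfile(qm, I, c(0.1, 0.25)), c(1.2, 1.5))
  expect_error(interpolateProfile(qm, I, c(0.005, 0.1)), "span")
})

# a small pool whose frames serve as planted truths
makeTestPool <- function(q = defaultQGrid(41)) {
  topo <- tinyTopology(nBeads = 24, radius = 9, linker = 10)
  pool <- runREMC(topo, ladder = ReplicaLadder(n = 4),
                  config = SamplerConfig(nSweeps = 150, saveEvery = 10, seed = 21))
  poolProfiles(pool, q = q, method = "direct")
}

test_that("best single model: planted truth, exhaustive ranking, empty pool", {
  pool <- makeTestPool()
  I <- pool@profiles[, 17]
  cv <- ScatteringCurve(pool@q, I, 1e-5 * I)
  best <- bestModel(pool, cv)
  expect_equal(best@members, 17L)
  expect_equal(best@chi2, 0, tolerance = 1e-10)

  set.seed(9)
  cvn <- ScatteringCurve(pool@q, I * (1 + rnorm(41, 0, 0.02)), 0.02 * I)
  best2 <- bestModel(pool, cvn)
  oracle <- vapply(seq_len(poolSize(pool)), function(k)
    lmChi2(pool@profiles[, k], cvn)$chi2, numeric(1))
  expect_equal(best2@members, which.min(oracle))
  expect_equal(best2@chi2, min(oracle), tolerance = 1e-9)

  empty <- new("ConformationPool", topology = pool@topology,
               coords = pool@coords[, , 0, drop = FALSE],
               meta = pool@meta[0, ], q = numeric(0),
               profiles = matrix(0, 0, 0), provenance = list())
  expect_error(bestModel(empty, cv), "empty pool")
})

test_that("minimal ensemble recovers planted mixtures with exhaustive cross-check", {
  pool <- makeTestPool()
  K <- poolSize(pool)
  # planted single: parsimony keeps size 1
  I <- pool@profiles[, 5]
  cv <- ScatteringCurve(pool@q, I, 1e-5 * I)
  ens <- minimalEnsemble(pool, cv, maxSize = 2)
  expect_equal(ens@members, 5L)
  expect_equal(ens@weights, 1)

  # planted 50:50 pair of distinct conformers + 1% noise
  mix <- 0.5 * pool@profiles[, 3] + 0.5 * pool@profiles[, 49]
  set.seed(12)
  s <- 0.01 * mix
  cvm <- ScatteringCurve(pool@q, mix + rnorm(41) * s, s)
  ens2 <- minimalEnsemble(pool, cvm, maxSize = 2)
  # independent exhaustive pair oracle via weighted lm
  pairs <- t(combn(K, 2))
  oc <- vapply(seq_len(nrow(pairs)), function(i)
    lmChi2(rowMeans(pool@profiles[, pairs[i, ]]), cvm)$chi2, numeric(1))
  bestPair <- pairs[which.min(oc), ]
  expect_setequal(ens2@members, bestPair)
  expect_equal(ens2@chi2, min(oc), tolerance = 1e-9)
  expect_equal(ens2@weights, c(0.5, 0.5))

  single <- bestModel(pool, cvm)
  expect_lte(ens2@chi2, single@chi2)
  expect_error(minimalEnsemble(pool, cvm, maxSize = K + 1), "exceeds pool")
})

test_that("weight optimization relaxes the equal-weight constraint consistently", {
  pool <- makeTestPool()
  mix <- 0.7 * pool@profiles[, 3] + 0.3 * pool@profiles[, 49]
  set.seed(13)
  s <- 0.01 * mix
  cvm <- ScatteringCurve(pool@q, mix + rnorm(41) * s, s)

  eq <- ensembleFit(pool, cvm, c(3, 49), "equal")
  op <- ensembleFit(pool, cvm, c(3, 49), "optimized")
  expect_lte(op@chi2, eq@chi2 + 1e-9)
  expect_equal(sum(op@weights), 1)
  expect_lt(abs(op@weights[match(3, op@members)] - 0.7), 0.1)

  # nesting monotonicity: adding members never hurts optimized fits
  set.seed(14)
  for (i in 1:5) {
    base <- sample(poolSize(pool), 2)
    extra <- sample(setdiff(seq_len(poolSize(pool)), base), 1)
    f2 <- ensembleFit(pool, cvm, base, "optimized")
    f3 <- ensembleFit(pool, cvm, c(base, extra), "optimized")
    expect_lte(f3@chi2, f2@chi2 * (1 + 1e-6) + 1e-9)
  }
})
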