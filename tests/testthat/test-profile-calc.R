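# Debye-formula scattering profiles

test_that("single- and two-bead profiles match closed forms", {
  q <- c(0, 0.05, 0.1, 0.3)
  one <- debyeProfile(matrix(c(1, 2, 3), 1), q = q)
  expect_equal(one$intensity, rep(1, 4))

  d <- 50
  two <- debyeProfile(rbind(c(0, 0, 0), c(d, 0, 0)), q = q)
  expect_equal(two$intensity, 2 * (1 + flexsaxs:::sincR(q * d)), tolerance = 1e-12)
  expect_equal(two$intensity[1], 4)
  expect_error(debyeProfile(matrix(0, 0, 3)), "empty")
})

test_that("fast paths agree with the brute-force double sum", {
  set.seed(3)
  X <- matrix(runif(600, 0, 100), ncol = 3)     # 200 beads in a 100 A box
  q <- defaultQGrid()
  direct <- debyeProfile(X, q, method = "direct")$intensity
  # independent O(N^2) oracle in R
  dd <- as.numeric(dist(X))
  oracle <- vapply(q, function(qi) 200 + 2 * sum(flexsaxs:::sincR(qi * dd)),
                   numeric(1))
  expect_lt(max(abs(direct - oracle) / oracle), 1e-10)

  hist <- debyeProfile(X, q, method = "histogram", binWidth = 0.1)$intensity
  expect_lt(max(abs(hist - oracle) / oracle), 1e-4)
})

test_that("forward-scattering sum rule and rigid-motion invariance hold", {
  set.seed(4)
  X <- matrix(rnorm(150, sd = 10), ncol = 3)
  ff <- FormFactorTable(perBead = runif(50, 0.5, 2))
  I <- debyeProfile(X, q = c(0, 0.1, 0.3), ff = ff)$intensity
  expect_equal(I[1], sum(rep_len(ff@perBead, 50))^2, tolerance = 1e-12)

  th <- 0.8
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  I2 <- debyeProfile(X %*% Rm + rep(3, 3), q = c(0, 0.1, 0.3), ff = ff)$intensity
  expect_lt(max(abs(I2 - I) / I), 1e-12)
})

test_that("Debye profile of a compact cloud reproduces its coordinate Rg", {
  set.seed(5)
  X <- matrix(rnorm(900, sd = 12), ncol = 3)
  rgCoord <- conformationMetrics(X)[["rg"]]
  q <- seq(0.002, 1.3 / rgCoord, length.out = 150)
  I <- debyeProfile(X, q)$intensity
  g <- guinierFit(ScatteringCurve(q, I, 1e-4 * I))
  expect_lt(abs(g@rg / rgCoord - 1), 0.01)
})

test_that("two-bead intensity stays within [0, 4] and averages to 2 at large qd", {
  d <- 200
  q <- seq(0.2, 0.5, length.out = 500)
  I <- debyeProfile(rbind(c(0, 0, 0), c(d, 0, 0)), q = q)$intensity
  expect_true(all(I >= 0 & I <= 4))
  expect_lt(abs(mean(I) - 2), 0.02)
})

test_that("q-dependent form factors modulate the profile", {
  X <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  shape <- function(q) exp(-q^2 * 4)
  q <- c(0, 0.1, 0.2)
  I <- debyeProfile(X, q, ff = FormFactorTable(qShape = shape))$intensity
  I1 <- debyeProfile(X, q)$intensity
  expect_equal(I, shape(q)^2 * I1, tolerance = 1e-12)
  # histogram path carries the same global shape factor
  Ih <- debyeProfile(X, q, ff = FormFactorTable(qShape = shape),
                     method = "histogram")$intensity
  expect_equal(Ih, I, tolerance = 1e-8)
})

test_that("pool profile caching matches per-model computation", {
  topo <- tinyTopology(nBeads = 20, radius = 8, linker = 6)
  pool <- runREMC(topo, ladder = ReplicaLadder(n = 2),
                  config = SamplerConfig(nSweeps = 40, saveEvery = 10, seed = 2))
  q <- defaultQGrid(31)
  pool <- poolProfiles(pool, q = q)
  expect_equal(dim(pool@profiles), c(31L, 8L))
  ref <- debyeProfile(pool@coords[, , 5], q = q, method = "histogram",
                      binWidth = 0.1)$intensity
  expect_equal(pool@profiles[, 5], ref)
  expect_true(all(pool@profiles > 0))
})
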