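# energy function, Metropolis sweeps, and replica exchange

test_that("energy terms evaluate to their hand-computed values", {
  # 3-bead linker at exact rest geometry: bonds at r0, angle at theta0
  topo <- buildTopology(list(LinkerSpec("L", 3)))
  th0 <- 2.12
  b3 <- c(3.8, 0, 0) + 3.8 * c(-cos(th0), sin(th0), 0)
  rest <- Conformation(topo, rbind(c(0, 0, 0), c(3.8, 0, 0), b3))
  m0 <- EnergyModel(torsionC = 0)
  expect_equal(calcEnergy(rest, m0), 0, tolerance = 1e-20)

  # one bond stretched by 1 A at k = 10 -> E = 5 kT
  topo2 <- buildTopology(list(LinkerSpec("L", 2)))
  stretched <- Conformation(topo2, rbind(c(0, 0, 0), c(4.8, 0, 0)))
  expect_equal(calcEnergy(stretched, EnergyModel(kStretch = 10, torsionC = 0)), 5)

  # overlapping rigid domains -> infinite-energy sentinel, not an error
  topo3 <- tinyTopology()
  lay <- flexsaxs:::topologyLayout(topo3)
  cc <- initialConformation(topo3, seed = 1)@coords
  memB <- which(lay$segId == 3)
  cc[memB, ] <- sweep(cc[memB, ], 2,
                      colMeans(cc[memB, ]) - colMeans(cc[lay$segId == 1, ]))
  expect_equal(calcEnergy(Conformation(topo3, cc)), Inf)
})

test_that("zero-temperature sweeps never raise the energy", {
  topo <- tinyTopology()
  conf <- initialConformation(topo, seed = 2)
  e0 <- calcEnergy(conf)
  res <- mcSweeps(conf, nSweeps = 50, beta = 1e8, seed = 3, saveEvery = 1)
  expect_true(all(diff(c(e0, res$energies)) <= 1e-9))
})

test_that("bond-length statistics match the Boltzmann closed form", {
  topo <- buildTopology(list(LinkerSpec("L", 2)))
  conf <- initialConformation(topo, seed = 1)
  k <- 10
  res <- mcSweeps(conf, EnergyModel(kStretch = k, kBend = 0, torsionC = 0,
                                    hardRadius = 0.1),
                  nSweeps = 1e5, beta = 1, seed = 2, saveEvery = 1)
  r <- sqrt(colSums((res$frames[1, , ] - res$frames[2, , ])^2))
  # oracle: 1-D integral of the radial density r^2 exp(-k/2 (r-r0)^2)
  f <- function(r) r^2 * exp(-k / 2 * (r - 3.8)^2)
  Z <- integrate(f, 0, 20)$value
  mu <- integrate(function(r) r * f(r), 0, 20)$value / Z
  v <- integrate(function(r) r^2 * f(r), 0, 20)$value / Z - mu^2
  expect_lt(abs(var(r) / v - 1), 0.05)
  expect_lt(abs(mean(r) / mu - 1), 0.01)
})

test_that("rigid domains stay internally rigid through sampling", {
  topo <- tinyTopology()
  conf <- initialConformation(topo, seed = 5)
  lay <- flexsaxs:::topologyLayout(topo)
  res <- mcSweeps(conf, nSweeps = 1000, beta = 1, seed = 6)
  for (seg in c(1, 3)) {
    mem <- which(lay$segId == seg)
    drift <- max(abs(dist(conf@coords[mem, ]) -
                     dist(res$conformation@coords[mem, ])))
    expect_lt(drift, 1e-6)
  }
  # chain integrity: linker bonds remain near bondLength under finite energy
  bl <- sqrt(rowSums((res$conformation@coords[lay$bonds[, 1], ] -
                      res$conformation@coords[lay$bonds[, 2], ])^2))
  expect_true(all(bl > 3.0 & bl < 4.6))
  expect_true(is.finite(res$energy))
})

test_that("pool size follows the closed-form schedule", {
  expect_equal(scheduleSize(20, 1e7, 1e3), 2e5)
  expect_error(scheduleSize(4, 1001, 10), "divisible")
  # property: random valid schedules
  set.seed(8)
  for (i in 1:20) {
    nr <- sample(1:6, 1); se <- sample(c(1, 2, 5, 10), 1)
    ns <- se * sample(1:20, 1)
    expect_equal(scheduleSize(nr, ns, se), nr * ns / se)
  }
  topo <- tinyTopology(nBeads = 20, radius = 8, linker = 6)
  pool <- runREMC(topo, ladder = ReplicaLadder(n = 3),
                  config = SamplerConfig(nSweeps = 120, saveEvery = 20, seed = 1))
  expect_equal(poolSize(pool), 3 * 120 / 20)
  expect_error(SamplerConfig(nSweeps = 100, saveEvery = 7), "divisible")
})

test_that("replica exchange: identical seeds reproduce, equal temperatures always swap", {
  topo <- tinyTopology(nBeads = 20, radius = 8, linker = 8)
  cfg <- SamplerConfig(nSweeps = 200, saveEvery = 20, seed = 31)
  p1 <- runREMC(topo, ladder = ReplicaLadder(n = 3), config = cfg)
  p2 <- runREMC(topo, ladder = ReplicaLadder(n = 3), config = cfg)
  expect_identical(p1@coords, p2@coords)
  expect_identical(p1@meta$energy, p2@meta$energy)

  # (numerically) degenerate ladder: delta-beta ~ 1e-12 -> all swaps accepted
  lad <- ReplicaLadder(temperatures = c(300, 300 * (1 + 1e-12)))
  p3 <- runREMC(topo, ladder = lad, config = cfg)
  ex <- p3@provenance$exchange
  expect_gt(sum(ex$attempts), 0)
  expect_equal(sum(ex$accepts), sum(ex$attempts))
})

test_that("exchange acceptance is strictly between 0 and 1 on an attached multidomain system", {
  mk <- function(nm) sphericalShellDomain(nm, radius = 10, nBeads = 40)
  scaf <- list(mk("CBM"), LinkerSpec("l1", 19), mk("Coh1"), LinkerSpec("l2", 19), mk("Coh2"))
  enz1 <- list(mk("Doc1"), LinkerSpec("l3", 12), mk("CD1"))
  enz2 <- list(mk("Doc2"), LinkerSpec("l4", 12), mk("CD2"))
  topo <- buildTopology(list(scaf, enz1, enz2),
                        attachments = rbind(c("Coh1", "Doc1"), c("Coh2", "Doc2")))
  lay <- flexsaxs:::topologyLayout(topo)
  expect_equal(length(lay$unitMembers), 5L)       # 7 domains, 2 fused pairs
  expect_equal(length(lay$components), 1L)

  pool <- runREMC(topo, ladder = ReplicaLadder(),  # default 20-replica ladder
                  config = SamplerConfig(nSweeps = 300, saveEvery = 50, seed = 13))
  ex <- pool@provenance$exchange
  rate <- sum(ex$accepts) / sum(ex$attempts)
  expect_gt(rate, 0)
  expect_lt(rate, 1)
})

test_that("heating expands a self-avoiding linker", {
  topo <- buildTopology(list(LinkerSpec("L", 30)))
  conf <- initialConformation(topo, seed = 5)
  rgMean <- function(beta, seed) {
    res <- mcSweeps(conf, nSweeps = 4e4, beta = beta, seed = seed, saveEvery = 20)
    mean(apply(res$frames[, , -(1:200)], 3,
               function(x) conformationMetrics(x)[["rg"]]))
  }
  expect_gte(rgMean(0.6, 8), rgMean(1.0, 7))      # beta = 300/T
})
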