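# coarse-grained representation: domains, linkers, topologies, conformations

test_that("domain and linker validity contracts hold", {
  expect_error(DomainSpec("x", matrix(rnorm(6), 2, 3)), ">= 3 beads")
  expect_error(DomainSpec("x", rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               "closer than 2.0")
  expect_error(LinkerSpec("l", 0), ">= 1")
  expect_error(LinkerSpec("l", 5, bondLength = 3.0), "3.6")
  d <- sphericalShellDomain("s", radius = 15, nBeads = 120)
  expect_equal(nrow(d@beads), 120)
  expect_gte(min(dist(d@beads)), 2.0)
})

test_that("topology bookkeeping: alternation, dof counting, attachments", {
  d1 <- sphericalShellDomain("D1", 10, 40)
  d2 <- sphericalShellDomain("D2", 10, 40)
  # single rigid domain: no flexible dof (6 overall rigid-body dof aside)
  expect_equal(mobileDof(buildTopology(list(d1))), 0L)

  # domain-linker(19)-domain mirrors the 19-residue dockerin linkers
  topo <- buildTopology(list(d1, LinkerSpec("L1", 19), d2))
  lay <- flexsaxs:::topologyLayout(topo)
  expect_equal(sum(lay$isLinker), 19L)
  expect_equal(nBeads(topo), 99L)
  # path C-anchor + 19 beads + N-anchor: 20 bonds, 19 angles, 18 torsions
  expect_equal(mobileDof(topo), 20L + 19L + 18L)

  expect_error(buildTopology(list(d1, d2)), "alternate")
  expect_error(buildTopology(list(d1, LinkerSpec("L1", 5), d2),
                             attachments = rbind(c("D1", "D2"))),
               "different chains")
  expect_error(buildTopology(list(list(d1), list(d2)),
                             attachments = rbind(c("D1", "NOPE"))),
               "undefined domain")
})

test_that("topology config files parse and error informatively", {
  topo <- readTopologyConfig(extdata("example_topology.cfg"))
  expect_s4_class(topo, "Topology")
  expect_equal(length(topo@chains[[1]]), 3L)

  f <- tempfile(fileext = ".cfg")
  writeLines(c("CHAIN", "DOMAIN missing not_a_file.pdb"), f)
  expect_error(readTopologyConfig(f), "not found")
  writeLines(c("CHAIN", "DOMAIN s sphere:12:60", "LINKER l 7",
               "DOMAIN t sphere:12:60"), f)
  topo2 <- readTopologyConfig(f)
  expect_equal(nBeads(topo2), 127L)
})

test_that("PDB domains read one bead per residue with error reporting", {
  d <- domainFromPDB("dA", extdata("synthetic_domain_A.pdb"), chain = "A")
  expect_equal(nrow(d@beads), 30)
  expect_lt(abs(max(dist(d@beads[1:2, ])) - 3.83), 0.05)

  # a residue with atoms but no CA must be named in the error
  pdb <- readLines(extdata("synthetic_domain_A.pdb"))
  hit <- grepl("^ATOM", pdb) & grepl(" CA ", pdb) & grepl("A  10 ", pdb)
  expect_equal(sum(hit), 1L)
  pdb[hit] <- sub(" CA ", " CB ", pdb[hit])
  f <- tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  expect_error(domainFromPDB("bad", f), "missing C-alpha in residue 10")
})

test_that("initial conformations are deterministic, exact and clash-free", {
  topo <- tinyTopology()
  c1 <- initialConformation(topo, seed = 9)
  c2 <- initialConformation(topo, seed = 9)
  expect_identical(c1@coords, c2@coords)
  c3 <- initialConformation(topo, seed = 10)
  expect_false(identical(c1@coords, c3@coords))

  # every linker virtual bond at exactly bondLength
  lay <- flexsaxs:::topologyLayout(topo)
  bl <- sqrt(rowSums((c1@coords[lay$bonds[, 1], ] - c1@coords[lay$bonds[, 2], ])^2))
  expect_equal(bl, rep(3.8, length(bl)), tolerance = 1e-12)

  # extent of the union is at least that of each domain alone
  dA <- conformationMetrics(lay$segObj[[1]]@beads)[["dmax"]]
  expect_gte(c1@dmax, dA)
  expect_true(is.finite(calcEnergy(c1)))
})

test_that("conformation metrics match brute-force oracles and are rigid-motion invariant", {
  expect_equal(unname(conformationMetrics(matrix(c(1, 2, 3), 1))), c(0, 0))
  expect_equal(unname(conformationMetrics(rbind(c(0, 0, 0), c(100, 0, 0)))),
               c(50, 100))

  set.seed(11)
  X <- matrix(runif(600, 0, 80), ncol = 3)
  m <- conformationMetrics(X)
  ctr <- colMeans(X)
  rgRef <- sqrt(mean(rowSums(sweep(X, 2, ctr)^2)))
  dmaxRef <- max(dist(X))                       # O(N^2) exhaustive
  expect_equal(m[["rg"]], rgRef, tolerance = 1e-10)
  expect_equal(m[["dmax"]], dmaxRef, tolerance = 1e-10)

  th <- 1.1
  Rm <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- conformationMetrics(X %*% Rm + rep(7, 3))
  expect_equal(m[["rg"]], m2[["rg"]], tolerance = 1e-10)
  expect_equal(m[["dmax"]], m2[["dmax"]], tolerance = 1e-10)
})

test_that("pool writing and reading round-trips through multi-model PDB", {
  topo <- tinyTopology(nBeads = 20, radius = 8, linker = 6)
  pool <- runREMC(topo, EnergyModel(), ReplicaLadder(n = 2),
                  SamplerConfig(nSweeps = 50, saveEvery = 10, seed = 4))
  expect_equal(poolSize(pool), 10L)
  pdb <- tempfile(fileext = ".pdb")
  writePool(pool, pdb)
  back <- readPool(topo, pdb)
  expect_equal(poolSize(back), 10L)
  expect_lt(max(abs(back@coords - pool@coords)), 1e-3)   # PDB keeps 3 decimals
  expect_equal(back@meta$energy, pool@meta$energy, tolerance = 1e-8)
  cf <- getConformation(back, 3)
  expect_s4_class(cf, "Conformation")
  expect_error(getConformation(back, 11), "out of range")
})
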