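test_that("radius of gyration matches closed forms", {
  expect_equal(radiusOfGyration(matrix(c(5, -2, 7), 1)), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(8, 0, 0))), 4)
  # 8 cube corners, edge a: Rg = a * sqrt(3) / 2
  a <- 10
  cube <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  expect_equal(radiusOfGyration(cube), a * sqrt(3) / 2)
})

test_that("energy terms match their closed forms", {
  p <- buildPartition(chromosomeSpec("c", 3500 * 3), 3500)
  g <- buildGeometry()
  pr <- energyParams(g)

  # straight chain at rest bond length: bond, bending, contact all zero
  x <- rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0))
  e <- totalEnergy(x, p, g, pr)
  expect_equal(e[["bond"]], 0)
  expect_equal(e[["bending"]], 0)
  expect_equal(e[["contact"]], 0)
  expect_equal(e[["confinement"]], 0)

  # right-angle kink: bending = kappa * (1 - cos 90) = kappa
  xk <- rbind(c(0, 0, 0), c(30, 0, 0), c(30, 30, 0))
  ek <- totalEnergy(xk, p, g, pr)
  expect_equal(ek[["bending"]], pr$kappa)

  # stretched bond: 1/2 k (d - b0)^2
  xs <- rbind(c(0, 0, 0), c(40, 0, 0), c(70, 0, 0))
  es <- totalEnergy(xs, p, g, pr)
  expect_equal(es[["bond"]], 0.5 * pr$kBond * 10^2)

  # contact spring: zero inside rest length, harmonic outside
  pairs <- cbind(1L, 3L)
  xin <- rbind(c(0, 0, 0), c(30, 0, 0), c(40, 0, 0))
  expect_equal(totalEnergy(xin, p, g, pr, pairs = pairs)[["contact"]], 0)
  d <- 200
  xout <- rbind(c(0, 0, 0), c(d / 2, 21, 0), c(d, 0, 0))
  expect_equal(totalEnergy(xout, p, g, pr, pairs = pairs)[["contact"]],
               0.5 * pr$kContact * (d - pr$contactRest)^2)

  # confinement: granule centre outside the allowed radius by delta
  delta <- 50
  xc <- matrix(c(0, 0, g@nuclearRadius - 15 + delta), 1)
  p1 <- buildPartition(chromosomeSpec("c", 3500), 3500)
  expect_equal(totalEnergy(xc, p1, g, pr)[["confinement"]],
               0.5 * pr$kConfine * delta^2)

  # excluded volume: non-bonded pair closer than one diameter
  xe <- rbind(c(0, 0, 0), c(0, 30, 0), c(20, 0, 0))
  expect_equal(totalEnergy(xe, p, g, pr)[["excluded"]],
               0.5 * pr$kExcluded * 10^2)

  # anchor well: flat inside the SPB zone, harmonic outside
  an <- anchorSet(1L, "SPB_zone", 0.1, p1)
  xinz <- matrix(c(0, 0, g@nuclearRadius - 100), 1)
  expect_equal(totalEnergy(xinz, p1, g, pr, anchors = an)[["anchor"]], 0)
  xoutz <- matrix(c(0, 0, 0), 1)  # distance R to SPB, zone radius 300
  expect_equal(totalEnergy(xoutz, p1, g, pr, anchors = an)[["anchor"]],
               0.5 * 0.1 * (g@nuclearRadius - g@spbZoneRadius)^2)
})

test_that("initConformation yields feasible, reproducible chains", {
  p <- tinyPartition()
  g <- buildGeometry(nucleolusRadius = 300)
  x1 <- initConformation(p, g, seed = 42)
  x2 <- initConformation(p, g, seed = 42)
  expect_identical(x1, x2)
  expect_equal(sum(hardViolations(x1, p, g)), 0)
  # bond lengths exactly one granule diameter at initialization
  d <- sqrt(rowSums((x1[-1, ] - x1[-10, ])^2))
  expect_equal(d, rep(30, 9), tolerance = 1e-12)
  # infeasible geometry errors out
  expect_error(initConformation(p, buildGeometry(nucleolusRadius = 1270,
                                                 nucleolusOffset = 0)),
               "initialization error")
})

test_that("anchored granules start inside their target regions", {
  p <- tinyPartition()
  g <- buildGeometry()
  an <- anchorSet(1L, "SPB_zone", 0.1, p)
  for (s in 1:5) {
    x <- initConformation(p, g, an, seed = s)
    expect_lte(sqrt(sum((x[1, ] - g@spbPosition)^2)), g@spbZoneRadius)
  }
})

test_that("mcOptimize with zero sweeps returns its input unchanged", {
  p <- tinyPartition()
  g <- buildGeometry()
  x0 <- initConformation(p, g, seed = 1)
  res <- mcOptimize(x0, p, g, energyParams(g, nTemps = 0))
  expect_identical(res$coords, x0)
})

test_that("annealing descends the energy surface and keeps feasibility", {
  p <- tinyPartition()
  g <- buildGeometry()
  pr <- fastParams(g)
  lowered <- 0
  for (s in 1:10) {
    x0 <- initConformation(p, g, seed = s)
    e0 <- totalEnergy(x0, p, g, pr, pairs = cbind(1L, 10L))[["total"]]
    res <- mcOptimize(x0, p, g, pr, pairs = cbind(1L, 10L), seed = s + 100)
    lowered <- lowered + (res$energy[["total"]] <= e0)
    expect_equal(sum(hardViolations(res$coords, p, g)), 0)
  }
  expect_gte(lowered, 9)
})

test_that("a strong contact spring pulls the pair to its rest length", {
  p <- tinyPartition()
  g <- buildGeometry()
  pr <- energyParams(g, kContact = 0.5, nTemps = 25, sweepsPerTemp = 40)
  x0 <- initConformation(p, g, seed = 3)
  res <- mcOptimize(x0, p, g, pr, pairs = cbind(1L, 10L), seed = 9)
  d <- sqrt(sum((res$coords[1, ] - res$coords[10, ])^2))
  expect_lte(d, 1.1 * pr$contactRest)
})

test_that("a tethered two-granule chromosome descends into its anchor well", {
  p <- buildPartition(chromosomeSpec("c", 7000), 3500)
  g <- buildGeometry()
  an <- anchorSet(1L, "SPB_zone", 0.2, p)
  pr <- energyParams(g, nTemps = 25, sweepsPerTemp = 60)
  # start away from the SPB on purpose: bypass the anchor-aware init
  x0 <- rbind(c(0, 0, -600), c(0, 0, -630))
  res <- mcOptimize(x0, p, g, pr, anchors = an, seed = 4)
  expect_lte(sqrt(sum((res$coords[1, ] - g@spbPosition)^2)),
             g@spbZoneRadius * 1.05)
})

test_that("free diffusion: zero energy surface accepts every move", {
  p <- buildPartition(chromosomeSpec("bead", 3500), 3500)
  g <- buildGeometry()
  pr0 <- energyParams(g, kBond = 0, persistenceLength = 0, kExcluded = 0,
                      kConfine = 0, kContact = 0, nTemps = 5,
                      sweepsPerTemp = 20, pCrank = 0, pPivot = 0,
                      pTrans = 0)
  x0 <- matrix(c(0, 0, 0), 1)
  res <- mcOptimize(x0, p, g, pr0, seed = 2)
  expect_equal(res$acceptRate, 1)
  expect_gt(sum(res$coords^2), 0)

  # mean-square displacement grows with the number of sweeps
  msd <- function(nt, seeds = 1:15) {
    mean(vapply(seeds, function(s) {
      pr <- energyParams(g, kBond = 0, persistenceLength = 0,
                         kExcluded = 0, kConfine = 0, kContact = 0,
                         nTemps = nt, sweepsPerTemp = 20, pCrank = 0,
                         pPivot = 0, pTrans = 0)
      sum(mcOptimize(x0, p, g, pr, seed = s)$coords^2)
    }, numeric(1)))
  }
  expect_gt(msd(8), msd(1))
})

test_that("ensembles are reproducible and structures distinct", {
  p <- tinyPartition()
  g <- buildGeometry()
  cs <- granuleContactSet(c(1, 2, 3), c(5, 7, 9), c(3, 2, 1), p)
  pr <- fastParams(g)
  e1 <- generateEnsemble(3, p, g, contactSet = cs, fraction = 1,
                         params = pr, masterSeed = 7, verbose = FALSE)
  e2 <- generateEnsemble(3, p, g, contactSet = cs, fraction = 1,
                         params = pr, masterSeed = 7, verbose = FALSE)
  expect_identical(e1@coords, e2@coords)
  expect_false(identical(e1@coords[, , 1], e1@coords[, , 2]))
  expect_equal(e1@modelKind, "contact_restrained")
  # random model drops contacts and anchors
  er <- generateEnsemble(2, p, g, contactSet = NULL, params = pr,
                         masterSeed = 8, verbose = FALSE)
  expect_equal(er@modelKind, "random")
  expect_equal(nrow(er@subsets[[1]]), 0)
})

test_that("contact restraints compact the genome relative to the random model", {
  cfg <- syntheticConfig()
  su <- syntheticSetup(cfg)
  cs <- readContacts(makeContacts(su$genome, cfg), su$partition,
                     verbose = FALSE)
  pr <- fastParams(su$geometry)
  eC <- generateEnsemble(4, su$partition, su$geometry, su$anchors, cs,
                         fraction = 0.1, params = pr, masterSeed = 21,
                         verbose = FALSE)
  eR <- generateEnsemble(4, su$partition, su$geometry, params = pr,
                         masterSeed = 22, verbose = FALSE)
  expect_lt(ensembleRg(eC), ensembleRg(eR))
})
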