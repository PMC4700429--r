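geomT <- buildGeometry()

test_that("rotational projection reduces to Pythagoras about the z axis", {
  # nuclear centre and SPB
  expect_equal(unlist(projectGranules(matrix(0, 1, 3), geomT)),
               c(z = 0, r = 0))
  expect_equal(unlist(projectGranules(matrix(c(0, 0, 1300), 1), geomT)),
               c(z = 1300, r = 0))
  # generic point: z = z0, r = sqrt(x^2 + y^2)
  pr <- projectGranules(rbind(c(300, 400, -200), c(-30, 40, 120)), geomT)
  expect_equal(pr$z, c(-200, 120))
  expect_equal(pr$r, c(500, 50))
})

test_that("density kernel matches the closed-form Gaussian at pixel centres", {
  p1 <- buildPartition(chromosomeSpec("c", 3500), 3500)
  sigma <- 15
  gg <- pombe3d:::.gridGeom(geomT, 266)
  # put the single granule exactly at a pixel centre
  iz <- 150L; ir <- 40L
  zg <- gg$zc[iz]; rg <- gg$rc[ir]
  # solve for 3D coords with that projection: x = rg on x-axis, z = zg
  coords <- matrix(c(rg, 0, zg), 1)
  ens <- ensembleFromCoords(list(coords), p1, geomT)
  dm <- densityMap(ens, weights = 1, sigma = sigma)
  expect_equal(dm@values[iz, ir], 1)  # exp(0)
  # neighbours decay by exp(-d^2 / (2 sigma^2))
  expect_equal(dm@values[iz + 1, ir],
               exp(-gg$dz^2 / (2 * sigma^2)))
  expect_equal(dm@values[iz, ir + 1],
               exp(-gg$dr^2 / (2 * sigma^2)))
  expect_equal(dm@values[iz + 2, ir + 3],
               exp(-((2 * gg$dz)^2 + (3 * gg$dr)^2) / (2 * sigma^2)))

  # zero weights give a zero grid
  expect_equal(sum(densityMap(ens, weights = 0)@values), 0)

  # duplicating a structure leaves the per-structure average unchanged
  ens2 <- ensembleFromCoords(list(coords, coords), p1, geomT)
  expect_equal(densityMap(ens2, weights = 1)@values, dm@values)

  expect_error(densityMap(ens, weights = c(1, 2)), "length")
})

test_that("kernel truncation loses < 0.1% of on-grid mass", {
  p <- tinyPartition()
  set.seed(8)
  coordsList <- lapply(1:2, function(s) latticeCoords(10, spacing = 80))
  ens <- ensembleFromCoords(coordsList, p, geomT)
  w <- rep(1, 10)
  truncated <- densityMap(ens, w)@values
  full <- bruteDensity(ens, w)
  expect_lt(abs(sum(truncated) - sum(full)) / sum(full), 1e-3)
  expect_equal(truncated, full, tolerance = 1e-3)
})

test_that("density maps are linear in the weights", {
  p <- tinyPartition()
  set.seed(9)
  coordsList <- list(latticeCoords(10, 70), latticeCoords(10, 90))
  ens <- ensembleFromCoords(coordsList, p, geomT)
  w1 <- c(1, 0, 1, 0, 0, 2, 0, 0, 0, 0)
  w2 <- c(0, 1, 0, 0, 3, 0, 0, 1, 0, 1)
  m1 <- densityMap(ens, w1)@values
  m2 <- densityMap(ens, w2)@values
  m12 <- densityMap(ens, w1 + w2)@values
  expect_equal(m12, m1 + m2, tolerance = 1e-12)

  # per-granule decomposition sums exactly to the total map
  perG <- Reduce(`+`, lapply(1:10, function(g) {
    w <- numeric(10); w[g] <- 1
    densityMap(ens, w)@values
  }))
  tot <- densityMap(ens, rep(1, 10))@values
  expect_equal(perG, tot, tolerance = 1e-9)
})

test_that("density grids are invariant under rotation about the axis", {
  p <- tinyPartition()
  set.seed(10)
  base <- latticeCoords(10, 75)
  th <- 1.1
  rot <- base %*% rbind(c(cos(th), -sin(th), 0),
                        c(sin(th), cos(th), 0),
                        c(0, 0, 1))
  m1 <- densityMap(ensembleFromCoords(list(base), p, geomT), rep(1, 10))
  m2 <- densityMap(ensembleFromCoords(list(rot), p, geomT), rep(1, 10))
  expect_equal(m1@values, m2@values, tolerance = 1e-9)
})

test_that("relative density divides by total plus Dempf", {
  p <- tinyPartition()
  ens <- ensembleFromCoords(list(latticeCoords(10, 80)), p, geomT)
  tot <- densityMap(ens, rep(1, 10))
  elem <- densityMap(ens, c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))

  # elem == total with dempf 0 gives 1 wherever total > 0
  r0 <- relativeDensity(tot, tot, dempf = 0)
  expect_true(all(abs(r0@values[tot@values > 0] - 1) < 1e-12))

  # zero element gives a zero map
  z <- relativeDensity(densityMap(ens, rep(0, 10)), tot)
  expect_equal(sum(z@values), 0)

  # spot arithmetic: elem / (total + dempf)
  r <- relativeDensity(elem, tot, dempf = 1.33)
  i <- which.max(elem@values)
  expect_equal(r@values[i], elem@values[i] / (tot@values[i] + 1.33))
  # default-Dempf spot value: element 2 over total 4 -> 2 / 5.33
  mkGrid <- function(x) new("DensityGrid", values = matrix(x, 3, 3),
                            deltaZ = 1, deltaR = 1, sigma = 15,
                            nStructures = 1L, nuclearRadius = 1300)
  expect_equal(relativeDensity(mkGrid(2), mkGrid(4))@values[1, 1],
               0.3752345, tolerance = 1e-6)

  bad <- new("DensityGrid", values = matrix(0, 2, 2), deltaZ = 1,
             deltaR = 1, sigma = 15, nStructures = 1L,
             nuclearRadius = 1300)
  expect_error(relativeDensity(elem, bad), "congruent")
})

test_that("top-signal contour encloses the target fraction greedily", {
  # uniform map: mask covers ~15% of pixels
  u <- new("RelativeDensityMap", values = matrix(1, 40, 40), dempf = 0,
           deltaZ = 1, deltaR = 1, nuclearRadius = 1300)
  m <- topSignalContour(u, 0.15)
  expect_equal(sum(m@mask), ceiling(0.15 * 1600))
  expect_lte(m@enclosedFraction, 0.15 + 1 / 1600 + 1e-12)

  # a single hot pixel holding > 15% of signal is the whole mask
  v <- matrix(1, 10, 10); v[5, 5] <- 30   # 30 / 129 ~ 23%
  hot <- new("RelativeDensityMap", values = v, dempf = 0, deltaZ = 1,
             deltaR = 1, nuclearRadius = 1300)
  mh <- topSignalContour(hot, 0.15)
  expect_equal(sum(mh@mask), 1)
  expect_true(mh@mask[5, 5])

  # greedy-prefix property on a random map: enclosed in
  # [fraction, fraction + max pixel share]
  set.seed(12)
  rv <- matrix(rexp(900), 30, 30)
  rm <- new("RelativeDensityMap", values = rv, dempf = 0, deltaZ = 1,
            deltaR = 1, nuclearRadius = 1300)
  mk <- topSignalContour(rm, 0.15)
  enc <- sum(rv[mk@mask]) / sum(rv)
  expect_gte(enc, 0.15)
  expect_lte(enc, 0.15 + max(rv) / sum(rv))
  # removing the weakest masked pixel drops below the target (minimality)
  vals <- sort(rv[mk@mask])
  expect_lt(enc - vals[1] / sum(rv), 0.15)

  # nesting: the 10% mask sits inside the 15% mask
  m10 <- topSignalContour(rm, 0.10)
  expect_true(all(!m10@mask | mk@mask))

  expect_warning(
    topSignalContour(new("RelativeDensityMap", values = matrix(0, 5, 5),
                         dempf = 0, deltaZ = 1, deltaR = 1,
                         nuclearRadius = 1300), 0.15), "all-zero")
})

test_that("difference maps are antisymmetric percentage points", {
  mk <- function(v) new("RelativeDensityMap", values = v, dempf = 1.33,
                        deltaZ = 1, deltaR = 1, nuclearRadius = 1300)
  a <- mk(matrix(c(0.30, 0.1, 0, 0.2), 2))
  b <- mk(matrix(c(0.20, 0.1, 0.05, 0), 2))
  d <- differenceMap(a, b)
  expect_equal(d[1, 1], 10)
  expect_equal(differenceMap(a, a), matrix(0, 2, 2))
  expect_equal(differenceMap(b, a), -d)
})

test_that("SPB-locus distances cover every structure", {
  p <- tinyPartition()
  # all granules at the nuclear centre: every distance equals R
  ctr <- matrix(0, 10, 3)
  ens <- ensembleFromCoords(list(ctr, ctr, ctr), p, geomT)
  d <- spbDistanceDistribution(ens, 4)
  expect_equal(d$sample, rep(1300, 3))
  expect_equal(d$mean, 1300)

  # single-structure ensemble gives a sample of size 1
  e1 <- ensembleFromCoords(list(latticeCoords(10, 60)), p, geomT)
  expect_length(spbDistanceDistribution(e1, 1)$sample, 1)
  expect_error(spbDistanceDistribution(e1, 99), "locus")
})

test_that("distribution overlap statistics behave at the extremes", {
  set.seed(14)
  x <- rnorm(400)
  ov <- distributionOverlap(x, x)
  expect_equal(ov$ks, 0)
  expect_equal(ov$overlap, 1)
  far <- distributionOverlap(x, x + 100)
  expect_equal(far$ks, 1)
  expect_equal(far$overlap, 0)
})
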