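#' Rotational projection of a conformation
#'
#' Projects granule centres onto the (z, r) half-plane of the
#' SPB-nucleolus axis: `z` is the signed projection onto the axis (nuclear
#' centre = 0, SPB side positive) and `r` the perpendicular distance to
#' the axis.  Nuclei are rotationally symmetric about this axis, so the
#' projection discards only the azimuthal angle.
#'
#' @param coords `n x 3` coordinate matrix (nm).
#' @param geometry a [NuclearGeometry-class].
#' @return data.frame with columns `z` and `r` (nm).
#' @export
projectGranules <- function(coords, geometry) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  coords <- as.matrix(coords)
  a <- geometry@axis
  z <- as.numeric(coords %*% a)
  perp <- coords - outer(z, a)
  data.frame(z = z, r = sqrt(rowSums(perp^2)))
}

# pixel-centre coordinates of the projection grid
.gridGeom <- function(geometry, nPixels = 266) {
  R <- geometry@nuclearRadius
  dz <- 2 * R / nPixels
  dr <- R / nPixels
  list(nPixels = nPixels, dz = dz, dr = dr,
       zc = -R + (seq_len(nPixels) - 0.5) * dz,
       rc = (seq_len(nPixels) - 0.5) * dr)
}

# truncated-Gaussian stamp of one projected granule: row/col index windows
# and the 1D kernel factors (the isotropic 2D kernel separates)
.kernelStamp <- function(zg, rg, gg, sigma, truncate = 4) {
  lim <- truncate * sigma
  i1 <- max(1L, ceiling((zg - lim - gg$zc[1]) / gg$dz + 1))
  i2 <- min(gg$nPixels, floor((zg + lim - gg$zc[1]) / gg$dz + 1))
  j1 <- max(1L, ceiling((rg - lim - gg$rc[1]) / gg$dr + 1))
  j2 <- min(gg$nPixels, floor((rg + lim - gg$rc[1]) / gg$dr + 1))
  if (i1 > i2 || j1 > j2) return(NULL)
  list(zi = i1:i2, ri = j1:j2,
       gz = exp(-(gg$zc[i1:i2] - zg)^2 / (2 * sigma^2)),
       gr = exp(-(gg$rc[j1:j2] - rg)^2 / (2 * sigma^2)))
}

#' Rotational-projection density grid
#'
#' Accumulates, for every structure in the ensemble, a 2D Gaussian kernel
#' (width `sigma`, default 15 nm = the granule radius) at each projected
#' granule position, weighted by the granule's signal value, on a
#' `nPixels x nPixels` grid covering z in [-R, R] and r in [0, R];
#' the sum is divided by the number of structures.  The kernel is the
#' unnormalized Gaussian `exp(-d^2 / (2 sigma^2))` evaluated at pixel
#' centres and truncated at `truncate * sigma`, so pixel values count
#' (kernel-smoothed) granule occurrences per structure.
#'
#' @param ensemble a [GenomeEnsemble-class].
#' @param weights a [GranuleSignal-class] (or numeric vector) of granule
#'   weights; `NULL` weights every granule 1 (total chromatin density).
#' @param sigma kernel width (nm).
#' @param nPixels grid size per side.
#' @param truncate kernel truncation radius in sigmas (`Inf` disables).
#' @return a [DensityGrid-class].
#' @export
densityMap <- function(ensemble, weights = NULL, sigma = 15,
                       nPixels = 266, truncate = 4) {
  stopifnot(is(ensemble, "GenomeEnsemble"))
  n <- nGranules(ensemble)
  w <- if (is.null(weights)) rep(1, n)
       else if (is(weights, "GranuleSignal")) weights@values
       else as.numeric(weights)
  if (length(w) != n)
    stop("weights length must equal the number of granules")
  gg <- .gridGeom(ensemble@geometry, nPixels)
  vals <- matrix(0, nPixels, nPixels)
  ns <- nStructures(ensemble)
  active <- which(w != 0)
  for (s in seq_len(ns)) {
    pr <- projectGranules(ensemble@coords[, , s], ensemble@geometry)
    for (g in active) {
      st <- .kernelStamp(pr$z[g], pr$r[g], gg, sigma, truncate)
      if (is.null(st)) next
      vals[st$zi, st$ri] <- vals[st$zi, st$ri] + w[g] * outer(st$gz, st$gr)
    }
  }
  new("DensityGrid", values = vals / ns, deltaZ = gg$dz, deltaR = gg$dr,
      sigma = sigma, nStructures = as.integer(ns),
      nuclearRadius = ensemble@geometry@nuclearRadius)
}

#' Relative density map
#'
#' Divides the element density pixel-wise by the total chromatin density
#' plus the `dempf` regularizer, removing the imprint of overall genome
#' compaction and taming discretization noise where absolute density is
#' low (e.g. the nuclear periphery).
#'
#' @param elem element [DensityGrid-class].
#' @param total total-chromatin [DensityGrid-class], congruent with
#'   `elem`.
#' @param dempf additive regularizer, in the same density units as the
#'   grids (default 1.33, roughly the density one granule contributes at
#'   the periphery).
#' @return a [RelativeDensityMap-class].
#' @export
relativeDensity <- function(elem, total, dempf = 1.33) {
  stopifnot(is(elem, "DensityGrid"), is(total, "DensityGrid"))
  if (!identical(dim(elem@values), dim(total@values)))
    stop("grids are not congruent")
  if (dempf < 0) stop("dempf must be >= 0")
  new("RelativeDensityMap", values = elem@values / (total@values + dempf),
      dempf = dempf, deltaZ = elem@deltaZ, deltaR = elem@deltaR,
      nuclearRadius = elem@nuclearRadius)
}

#' Top-signal contour mask
#'
#' Marks the smallest set of highest-valued pixels whose summed signal
#' reaches `fraction` of the map total (default 15%).  Pixels are taken in
#' decreasing value order, ties broken by pixel index (stable), so the
#' enclosed signal exceeds the target by at most one pixel's share.
#'
#' @param map a [RelativeDensityMap-class] (or [DensityGrid-class]).
#' @param fraction signal fraction to enclose, in (0, 1).
#' @return a [ContourMask-class].
#' @export
topSignalContour <- function(map, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  v <- gridValues(map)
  tot <- sum(v)
  mask <- matrix(FALSE, nrow(v), ncol(v))
  if (tot <= 0) {
    warning("all-zero map: empty contour mask")
    return(new("ContourMask", mask = mask, fraction = fraction,
               enclosedFraction = 0))
  }
  ord <- order(v, decreasing = TRUE)   # stable: ties in pixel-index order
  cs <- cumsum(v[ord])
  k <- which(cs >= fraction * tot)[1]
  mask[ord[seq_len(k)]] <- TRUE
  new("ContourMask", mask = mask, fraction = fraction,
      enclosedFraction = cs[k] / tot)
}

#' Difference of two relative density maps
#'
#' Pixel-wise percentage-point change `100 * (a - b)`; antisymmetric and
#' defined everywhere, including pixels where `b` is zero.
#'
#' @param a,b congruent [RelativeDensityMap-class] objects.
#' @return signed matrix of % change per pixel.
#' @export
differenceMap <- function(a, b) {
  stopifnot(is(a, "RelativeDensityMap"), is(b, "RelativeDensityMap"))
  if (!identical(dim(a@values), dim(b@values)))
    stop("maps are not congruent")
  100 * (a@values - b@values)
}

#' Per-granule impact on a density difference
#'
#' Quantifies how much each granule contributes to the density change
#' between two ensembles inside a region of interest.  The region is the
#' set of pixels within `regionRadius` of the SPB-nucleolus axis whose
#' element-level difference map (`weights` in A vs B) has the selected
#' sign.  For each granule separately, relative density maps are built in
#' both ensembles (element = that granule alone), differenced, and
#' averaged over the selected pixels; values are percentage points, as in
#' [differenceMap()].
#'
#' @param ensA,ensB two [GenomeEnsemble-class] objects sharing partition
#'   and geometry.
#' @param weights [GranuleSignal-class] of the element whose change
#'   defines the selected pixels.
#' @param regionRadius radial cut-off from the axis (nm, default 670).
#' @param pixelSign `"decreased"` or `"increased"`: keep pixels where the
#'   element difference (A - B) is negative or positive.
#' @param dempf regularizer for the relative maps.
#' @param sigma,nPixels,truncate grid settings, as in [densityMap()].
#' @return an [ImpactProfile-class].
#' @export
granuleImpact <- function(ensA, ensB, weights,
                          regionRadius = 670,
                          pixelSign = c("decreased", "increased"),
                          dempf = 1.33, sigma = 15, nPixels = 266,
                          truncate = 4) {
  pixelSign <- match.arg(pixelSign)
  stopifnot(is(ensA, "GenomeEnsemble"), is(ensB, "GenomeEnsemble"))
  if (nGranules(ensA) != nGranules(ensB))
    stop("ensembles must share one partition")
  n <- nGranules(ensA)

  totA <- densityMap(ensA, NULL, sigma, nPixels, truncate)
  totB <- densityMap(ensB, NULL, sigma, nPixels, truncate)
  elemA <- densityMap(ensA, weights, sigma, nPixels, truncate)
  elemB <- densityMap(ensB, weights, sigma, nPixels, truncate)
  diffElem <- differenceMap(relativeDensity(elemA, totA, dempf),
                            relativeDensity(elemB, totB, dempf))

  gg <- .gridGeom(ensA@geometry, nPixels)
  inRegion <- matrix(rep(gg$rc <= regionRadius, each = nPixels),
                     nPixels, nPixels)
  sel <- inRegion & (if (pixelSign == "decreased") diffElem < 0
                     else diffElem > 0)
  nSel <- sum(sel)
  if (nSel == 0L) {
    warning("no pixels with ", pixelSign, " density in the region; ",
            "impact profile is all zero")
    return(new("ImpactProfile", values = numeric(n),
               regionRadius = regionRadius, pixelSign = pixelSign,
               nPixels = 0L))
  }

  # mean over selected pixels of 100 * (D_g^A/(totA+dempf) - D_g^B/(totB+dempf))
  # computed as weighted sums of the per-granule kernel stamps
  wA <- matrix(0, nPixels, nPixels); wB <- wA
  wA[sel] <- 100 / (nSel * (totA@values[sel] + dempf))
  wB[sel] <- 100 / (nSel * (totB@values[sel] + dempf))
  acc <- function(ens, wmap) {
    out <- numeric(n)
    for (s in seq_len(nStructures(ens))) {
      pr <- projectGranules(ens@coords[, , s], ens@geometry)
      for (g in seq_len(n)) {
        st <- .kernelStamp(pr$z[g], pr$r[g], gg, sigma, truncate)
        if (is.null(st)) next
        sub <- wmap[st$zi, st$ri, drop = FALSE]
        out[g] <- out[g] + as.numeric(st$gz %*% sub %*% st$gr)
      }
    }
    out / nStructures(ens)
  }
  new("ImpactProfile", values = acc(ensA, wA) - acc(ensB, wB),
      regionRadius = regionRadius, pixelSign = pixelSign,
      nPixels = as.integer(nSel))
}

#' SPB-locus distance distribution
#'
#' Distance from the SPB to one locus (granule) in every structure of an
#' ensemble, with summary statistics, for validation against microscopy
#' distance measurements.
#'
#' @param ensemble a [GenomeEnsemble-class].
#' @param locus global granule index.
#' @param breaks histogram break count.
#' @return list with `sample` (nm, one per structure), `mean`, `sd` and
#'   `hist` (a `hist()` object, not plotted).
#' @export
spbDistanceDistribution <- function(ensemble, locus, breaks = 30) {
  stopifnot(is(ensemble, "GenomeEnsemble"))
  n <- nGranules(ensemble)
  if (locus < 1 || locus > n) stop("locus index outside the partition")
  spb <- ensemble@geometry@spbPosition
  d <- apply(ensemble@coords[locus, , , drop = FALSE], 3,
             function(x) sqrt(sum((x - spb)^2)))
  list(sample = d, mean = mean(d), sd = stats::sd(d),
       hist = graphics::hist(d, breaks = breaks, plot = FALSE))
}

#' Compare two distance distributions
#'
#' Two-sample Kolmogorov-Smirnov distance plus the histogram overlap
#' coefficient (shared area of the two normalized histograms on a common
#' grid) -- a symmetric pair of agreement measures for validating modelled
#' SPB-locus distances against reference samples.
#'
#' @param x,y numeric samples.
#' @param breaks number of common histogram bins.
#' @return list with `ks` (KS distance in [0, 1]) and `overlap`
#'   (coefficient in [0, 1], 1 = identical histograms).
#' @export
distributionOverlap <- function(x, y, breaks = 30) {
  ks <- suppressWarnings(
    unname(stats::ks.test(x, y)$statistic))
  rng <- range(c(x, y))
  br <- seq(rng[1], rng[2], length.out = breaks + 1)
  px <- graphics::hist(x, breaks = br, plot = FALSE)$counts / length(x)
  py <- graphics::hist(y, breaks = br, plot = FALSE)$counts / length(y)
  list(ks = ks, overlap = sum(pmin(px, py)))
}
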