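#' Energy and annealing parameters
#'
#' Collects the energy-surface constants and the Metropolis annealing
#' schedule in one list.  Energies are in units of kT; lengths in nm.
#' The functional forms are: harmonic bonds at rest length one granule
#' diameter, a Kratky-Porod bending term `kappa * (1 - cos theta)` with
#' `kappa` equal to the persistence length in granule units, soft-core
#' quadratic excluded-volume and confinement penalties, flat-bottomed
#' anchor wells, and flat-bottomed contact springs (zero inside
#' `contactRest`, harmonic outside).  Hard versions of the geometric
#' constraints (confinement, nucleolar exclusion, bond window 0.8-1.2 x
#' rest, excluded-volume floor at 99% of the granule diameter) are
#' enforced by move rejection during optimization.
#'
#' @param geometry a [NuclearGeometry-class]; sets the bond length.
#' @param kBond bond spring constant (kT/nm^2).
#' @param persistenceLength bending stiffness in granule units (default 3).
#' @param kExcluded soft-core excluded-volume scale (kT/nm^2).
#' @param kConfine confinement / nucleolar-exclusion penalty scale.
#' @param kContact contact spring constant (kT/nm^2).
#' @param contactRest contact rest length (nm); default 1.5 granule
#'   diameters, flat-bottomed so restrained pairs are pulled to "touching"
#'   rather than collapsed.
#' @param t0,alpha,nTemps geometric cooling schedule `T_k = t0 * alpha^k`.
#' @param sweepsPerTemp Monte Carlo sweeps per temperature (one sweep =
#'   `nGranules` move attempts).
#' @param maxStep maximum single-granule displacement (nm).
#' @param pCrank,pPivot,pTrans move-mix probabilities for crankshaft,
#'   chain-pivot and rigid chromosome-translation moves (remainder:
#'   single-granule displacement).
#' @param pivotMaxAngle,transMaxStep collective-move amplitudes.
#' @return named list of parameters.
#' @export
energyParams <- function(geometry = buildGeometry(),
                         kBond = 2,
                         persistenceLength = 5,
                         kExcluded = 2,
                         kConfine = 1,
                         kContact = 0.003,
                         contactRest = 1.5 * geometry@granuleDiameter,
                         t0 = 2, alpha = 0.85, nTemps = 30,
                         sweepsPerTemp = 60,
                         maxStep = 9,
                         pCrank = 0.2, pPivot = 0.1, pTrans = 0.02,
                         pivotMaxAngle = pi / 3,
                         transMaxStep = 120) {
  stopifnot(kBond >= 0, persistenceLength >= 0, kExcluded >= 0,
            kConfine >= 0, kContact >= 0, nTemps >= 0, sweepsPerTemp >= 0)
  list(kBond = kBond, bondLength = geometry@granuleDiameter,
       kappa = persistenceLength, kExcluded = kExcluded,
       kConfine = kConfine, kContact = kContact, contactRest = contactRest,
       t0 = t0, alpha = alpha, nTemps = as.integer(nTemps),
       sweepsPerTemp = as.integer(sweepsPerTemp), maxStep = maxStep,
       pCrank = pCrank, pPivot = pPivot, pTrans = pTrans,
       pivotMaxAngle = pivotMaxAngle, transMaxStep = transMaxStep)
}

# chromosome id (integer, grouped) per granule
.chromIds <- function(partition) {
  chrom <- as.character(GenomicRanges::seqnames(partition@granules))
  as.integer(factor(chrom, levels = unique(chrom)))
}

.geomList <- function(geometry) {
  list(R = geometry@nuclearRadius, rg = geometry@granuleDiameter / 2,
       nucRadius = geometry@nucleolusRadius,
       nucCenter = geometry@nucleolusCenter, spb = geometry@spbPosition,
       spbZoneRadius = geometry@spbZoneRadius,
       peripheryWidth = geometry@peripheryWidth,
       nucleolarSurfaceWidth = geometry@nucleolarSurfaceWidth)
}

.anchorCodes <- function(anchors) {
  codes <- c(SPB_zone = 1L, periphery = 2L, nucleolar_surface = 3L)
  list(g = anchors@granule, t = unname(codes[anchors@target]), k = anchors@k)
}

.emptyPairs <- function() matrix(integer(), ncol = 2,
                                 dimnames = list(NULL, c("i", "j")))

# distance from a point to an anchor region (0 inside)
.anchorDistance <- function(x, target, geometry) {
  R <- geometry@nuclearRadius
  if (target == "SPB_zone") {
    max(0, sqrt(sum((x - geometry@spbPosition)^2)) - geometry@spbZoneRadius)
  } else if (target == "periphery") {
    max(0, (R - geometry@peripheryWidth) - sqrt(sum(x^2)))
  } else {
    lim <- geometry@nucleolusRadius + geometry@nucleolarSurfaceWidth +
      geometry@granuleDiameter / 2
    max(0, sqrt(sum((x - geometry@nucleolusCenter)^2)) - lim)
  }
}

#' Initialize a conformation
#'
#' Grows each chromosome as a self-avoiding random walk with bond length
#' one granule diameter, inside the nucleus and outside the nucleolus.
#' When a chromosome carries anchors, growth starts at its first anchored
#' granule, placed inside its target region, and subsequent steps are
#' biased towards the regions of upcoming anchors (best of several trial
#' directions), so anchored granules start in or near their wells.
#'
#' @param partition a [GranulePartition-class].
#' @param geometry a [NuclearGeometry-class].
#' @param anchors an [AnchorSet-class] (may be empty).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param maxRetries placement retries per granule before restarting the
#'   chromosome, and chromosome restarts before failing.
#' @return `nGranules x 3` coordinate matrix (nm).
#' @export
initConformation <- function(partition, geometry,
                             anchors = anchorSet(), seed = NULL,
                             maxRetries = 200) {
  if (!is.null(seed)) set.seed(seed)
  n <- nGranules(partition)
  chromId <- .chromIds(partition)
  R <- geometry@nuclearRadius
  rg <- geometry@granuleDiameter / 2
  b <- geometry@granuleDiameter
  rmax <- R - rg
  nucC <- geometry@nucleolusCenter
  nucLim <- geometry@nucleolusRadius + rg
  if (rmax <= nucLim - sqrt(sum(nucC^2)) || rmax < b)
    stop("initialization error: geometry leaves no room for granules")

  okPoint <- function(x) {
    if (sqrt(sum(x^2)) > rmax) return(FALSE)
    if (geometry@nucleolusRadius > 0 &&
        sqrt(sum((x - nucC)^2)) < nucLim) return(FALSE)
    TRUE
  }
  # a bonded neighbour sits at exactly distance b, so the strict 0.999*b
  # threshold flags only genuine (non-bonded) overlaps
  clash <- function(x, placed) {
    if (!nrow(placed)) return(FALSE)
    d2 <- (placed[, 1] - x[1])^2 + (placed[, 2] - x[2])^2 +
      (placed[, 3] - x[3])^2
    any(d2 < (0.999 * b)^2)
  }
  randInRegion <- function(target) {
    for (tr in seq_len(1000)) {
      x <- stats::runif(3, -rmax, rmax)
      if (!okPoint(x)) next
      if (is.null(target) || .anchorDistance(x, target, geometry) == 0)
        return(x)
    }
    stop("initialization error: cannot place a granule",
         if (!is.null(target)) paste0(" in region ", target))
  }
  anchorTarget <- rep(NA_character_, n)
  if (length(anchors@granule))
    anchorTarget[anchors@granule] <- anchors@target

  coords <- matrix(NA_real_, n, 3)
  placedRows <- integer(0)
  for (c in unique(chromId)) {
    idx <- which(chromId == c)
    anch <- idx[!is.na(anchorTarget[idx])]
    startG <- if (length(anch)) anch[1] else idx[1]
    for (restart in seq_len(maxRetries)) {
      ok <- TRUE
      coords[idx, ] <- NA_real_
      placed <- coords[placedRows, , drop = FALSE]
      x0 <- randInRegion(if (!is.na(anchorTarget[startG]))
        anchorTarget[startG] else NULL)
      tries <- 0
      while (clash(x0, placed) && tries < maxRetries) {
        x0 <- randInRegion(if (!is.na(anchorTarget[startG]))
          anchorTarget[startG] else NULL)
        tries <- tries + 1
      }
      if (tries >= maxRetries) { ok <- FALSE }
      coords[startG, ] <- x0
      chainPlaced <- matrix(x0, 1)
      # grow in both directions from the start granule
      for (dir in c(1L, -1L)) {
        if (!ok) break
        seqg <- if (dir == 1L) idx[idx > startG] else rev(idx[idx < startG])
        prev <- startG
        for (gidx in seqg) {
          # next anchored granule ahead in this direction; bias growth
          # toward its region only when the remaining chain barely covers
          # the distance (otherwise grow freely, letting arms splay)
          ahead <- if (dir == 1L) anch[anch >= gidx] else rev(anch[anch <= gidx])
          tgt <- NA_character_
          if (length(ahead)) {
            reach <- 0.7 * b * (abs(ahead[1] - gidx) + 1)
            if (.anchorDistance(coords[prev, ], anchorTarget[ahead[1]],
                                geometry) > reach)
              tgt <- anchorTarget[ahead[1]]
          }
          best <- NULL; bestScore <- Inf
          for (tr in seq_len(maxRetries)) {
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            x <- coords[prev, ] + b * u
            if (!okPoint(x)) next
            if (clash(x, rbind(placed, chainPlaced))) next
            score <- if (is.na(tgt)) 0 else
              .anchorDistance(x, tgt, geometry)
            if (score < bestScore) { best <- x; bestScore <- score }
            # unbiased growth needs one sample; biased keeps the best of 8
            if (is.na(tgt) || tr >= 8) break
          }
          if (is.null(best)) { ok <- FALSE; break }
          coords[gidx, ] <- best
          chainPlaced <- rbind(chainPlaced, best)
          prev <- gidx
        }
      }
      if (ok) break
      if (restart == maxRetries)
        stop("initialization error: placement failed; geometry too crowded")
    }
    placedRows <- c(placedRows, idx)
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  coords
}

#' Total energy of a conformation
#'
#' Evaluates the full energy surface with a per-term breakdown (bond,
#' bending, excluded volume, confinement, nucleolar exclusion, anchors,
#' contact springs).
#'
#' @param coords `nGranules x 3` coordinate matrix (nm).
#' @param partition a [GranulePartition-class].
#' @param geometry a [NuclearGeometry-class].
#' @param params [energyParams()] list.
#' @param pairs two-column matrix of restrained granule pairs (may be
#'   empty).
#' @param anchors an [AnchorSet-class].
#' @return named numeric vector of term energies plus `total` (kT).
#' @export
totalEnergy <- function(coords, partition, geometry,
                        params = energyParams(geometry),
                        pairs = NULL, anchors = anchorSet()) {
  if (is.null(pairs)) pairs <- .emptyPairs()
  ac <- .anchorCodes(anchors)
  cpp_total_energy(coords, .chromIds(partition), .geomList(geometry),
                   params, pairs, ac$g, ac$t, ac$k)
}

#' Optimize a conformation by simulated annealing
#'
#' Metropolis Monte Carlo with geometric cooling.  The move set mixes
#' single-granule displacements, crankshaft rotations, chain pivots and
#' rigid chromosome translations.  Hard constraints (confinement,
#' nucleolar exclusion, bond window, excluded-volume floor) are enforced
#' by rejecting violating moves throughout, so a feasible input yields a
#' feasible output.
#'
#' @inheritParams totalEnergy
#' @param seed integer seed.
#' @return list with `coords`, per-term `energy` and the overall
#'   `acceptRate`.
#' @export
mcOptimize <- function(coords, partition, geometry,
                       params = energyParams(geometry),
                       pairs = NULL, anchors = anchorSet(), seed = NULL) {
  if (is.null(pairs)) pairs <- .emptyPairs()
  if (!is.null(seed)) set.seed(seed)
  if (params$nTemps == 0L || params$sweepsPerTemp == 0L)
    return(list(coords = coords,
                energy = totalEnergy(coords, partition, geometry, params,
                                     pairs, anchors),
                acceptRate = NA_real_))
  viol <- hardViolations(coords, partition, geometry, params)
  if (sum(viol) > 0)
    stop("mcOptimize requires a feasible starting conformation (",
         paste(names(viol)[viol > 0], collapse = ", "), " violated)")
  ac <- .anchorCodes(anchors)
  sched <- params[c("t0", "alpha", "nTemps", "sweepsPerTemp", "maxStep",
                    "pCrank", "pPivot", "pTrans", "pivotMaxAngle",
                    "transMaxStep")]
  res <- cpp_mc_optimize(coords, .chromIds(partition), .geomList(geometry),
                         params, pairs, ac$g, ac$t, ac$k, sched)
  dimnames(res$coords) <- list(NULL, c("x", "y", "z"))
  res
}

#' Count hard-constraint violations of a conformation
#'
#' @inheritParams totalEnergy
#' @return named integer vector: confinement, nucleolus, bond (outside the
#'   0.8-1.2 x rest window) and excluded-volume (non-bonded pair closer
#'   than 99% of the granule diameter) violation counts.
#' @export
hardViolations <- function(coords, partition, geometry,
                           params = energyParams(geometry)) {
  cpp_hard_violations(coords, .chromIds(partition), .geomList(geometry),
                      params)
}

#' Generate an ensemble of genome structures
#'
#' Produces `n` independently optimized conformations.  For the
#' contact-restrained model each structure is restrained by its own
#' frequency-proportional contact subset (via [assignSubsets()], which also
#' guarantees every captured pair appears in at least one structure).  The
#' random model (`modelKind = "random"`, or an empty/`NULL` contact set)
#' drops contacts and anchors and keeps only chain connectivity and nuclear
#' confinement.
#'
#' @param n number of structures (>= 1).
#' @param partition,geometry,anchors model setup.
#' @param contactSet a [GranuleContactSet-class], or `NULL` for the random
#'   model.
#' @param fraction contact-subset fraction per structure.
#' @param params [energyParams()] list.
#' @param masterSeed integer; every per-structure seed derives from it, so
#'   a fixed master seed reproduces the ensemble exactly.
#' @param modelKind `"contact_restrained"` or `"random"`.
#' @param verbose log subset coverage messages.
#' @return a [GenomeEnsemble-class].
#' @export
generateEnsemble <- function(n, partition, geometry,
                             anchors = anchorSet(), contactSet = NULL,
                             fraction = 0.1,
                             params = energyParams(geometry),
                             masterSeed = 1,
                             modelKind = if (is.null(contactSet))
                               "random" else "contact_restrained",
                             verbose = TRUE) {
  stopifnot(n >= 1)
  if (modelKind == "random") {
    contactSet <- NULL
    anchors <- anchorSet()
  }
  set.seed(masterSeed)
  seeds <- sample.int(2147483646L, n)
  subsets <- if (!is.null(contactSet))
    assignSubsets(contactSet, fraction, n, seed = masterSeed,
                  verbose = verbose)
  else rep(list(.emptyPairs()), n)

  ng <- nGranules(partition)
  coords <- array(NA_real_, c(ng, 3, n))
  energies <- numeric(n)
  for (s in seq_len(n)) {
    x0 <- initConformation(partition, geometry, anchors, seed = seeds[s])
    res <- mcOptimize(x0, partition, geometry, params,
                      pairs = subsets[[s]], anchors = anchors,
                      seed = seeds[s] + 1L)
    coords[, , s] <- res$coords
    energies[s] <- res$energy[["total"]]
  }
  cfg <- paste(ng, geometry@nuclearRadius, fraction, params$nTemps,
               params$sweepsPerTemp, modelKind, masterSeed, sep = "|")
  new("GenomeEnsemble", coords = coords, seeds = seeds, subsets = subsets,
      modelKind = modelKind, partition = partition, geometry = geometry,
      energies = energies,
      configHash = sprintf("%08x", sum(utf8ToInt(cfg) *
                                         seq_along(utf8ToInt(cfg))) %% 4294967291))
}

#' Radius of gyration
#'
#' Root-mean-square distance of granule centres from their centroid.
#'
#' @param coords `n x 3` coordinate matrix.
#' @return Rg in the coordinate units (nm).
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(10, 0, 0)))  # 5
#' @export
radiusOfGyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stop("need at least one granule")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Mean radius of gyration of an ensemble
#'
#' @param ensemble a [GenomeEnsemble-class].
#' @return mean Rg over structures (nm).
#' @export
ensembleRg <- function(ensemble) {
  mean(apply(ensemble@coords, 3, radiusOfGyration))
}

#' Export an ensemble as XYZ-style text
#'
#' Writes one whitespace-separated block per structure (granule index,
#' chromosome, x, y, z) for external visualization.
#'
#' @param ensemble a [GenomeEnsemble-class].
#' @param path output file.
#' @export
writeEnsembleXYZ <- function(ensemble, path) {
  chrom <- as.character(GenomicRanges::seqnames(
    ensemble@partition@granules))
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seq_len(nStructures(ensemble))) {
    cat(sprintf("# structure %d seed %d\n", s, ensemble@seeds[s]),
        file = con)
    xyz <- ensemble@coords[, , s]
    utils::write.table(data.frame(seq_len(nrow(xyz)), chrom, xyz), con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
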