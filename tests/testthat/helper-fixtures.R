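# Shared fixtures: everything is generated in code at test time.

# one small chromosome, exact division into 10 granules
tinyPartition <- function(len = 35000, granuleBp = 3500, name = "chrT") {
  buildPartition(chromosomeSpec(name, len), granuleBp = granuleBp)
}

# partition with several single-granule chromosomes (unlinked beads)
beadPartition <- function(nBeads = 50, granuleBp = 3500) {
  chroms <- lapply(seq_len(nBeads), function(i)
    chromosomeSpec(paste0("bead", i), granuleBp))
  buildPartition(chroms, granuleBp = granuleBp)
}

# a fast annealing schedule for small fixtures
fastParams <- function(geometry, ...) {
  energyParams(geometry, nTemps = 15, sweepsPerTemp = 20, ...)
}

# brute-force untruncated density grid for one ensemble + weights:
# independent of the kernel-stamping implementation
bruteDensity <- function(ensemble, weights, sigma = 15, nPixels = 266) {
  R <- ensemble@geometry@nuclearRadius
  dz <- 2 * R / nPixels
  dr <- R / nPixels
  zc <- -R + (seq_len(nPixels) - 0.5) * dz
  rc <- (seq_len(nPixels) - 0.5) * dr
  vals <- matrix(0, nPixels, nPixels)
  w <- if (is(weights, "GranuleSignal")) weights@values else weights
  for (s in seq_len(nStructures(ensemble))) {
    pr <- projectGranules(ensemble@coords[, , s], ensemble@geometry)
    for (g in which(w != 0)) {
      gz <- exp(-(zc - pr$z[g])^2 / (2 * sigma^2))
      gr <- exp(-(rc - pr$r[g])^2 / (2 * sigma^2))
      vals <- vals + w[g] * outer(gz, gr)
    }
  }
  vals / nStructures(ensemble)
}

# exact inclusion probabilities for successive weighted draws without
# replacement (renormalising after each draw), by full enumeration
enumInclusionProbs <- function(weights, k) {
  n <- length(weights)
  incl <- numeric(n)
  recurse <- function(remaining, probSoFar, depth, chosen) {
    if (depth == k) {
      incl[chosen] <<- incl[chosen] + probSoFar
      return(invisible())
    }
    wsum <- sum(weights[remaining])
    for (i in remaining) {
      recurse(setdiff(remaining, i), probSoFar * weights[i] / wsum,
              depth + 1, c(chosen, i))
    }
  }
  recurse(seq_len(n), 1, 0, integer(0))
  incl
}

# build a GenomeEnsemble directly from a list of coordinate matrices,
# bypassing the sampler (for density/overlap fixtures)
ensembleFromCoords <- function(coordsList, partition, geometry,
                               modelKind = "contact_restrained") {
  n <- length(coordsList)
  arr <- array(0, c(nrow(coordsList[[1]]), 3, n))
  for (s in seq_len(n)) arr[, , s] <- coordsList[[s]]
  new("GenomeEnsemble", coords = arr, seeds = seq_len(n),
      subsets = rep(list(matrix(integer(), ncol = 2)), n),
      modelKind = modelKind, partition = partition, geometry = geometry,
      energies = numeric(n), configHash = "fixture")
}

# place n granules on a loose 3D lattice inside the nucleus (no overlaps,
# ignores bonds; fine for density fixtures)
latticeCoords <- function(n, spacing = 60, offset = c(0, 0, 0)) {
  side <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1
  cbind(offset[1] + spacing * (idx %% side - side / 2),
        offset[2] + spacing * ((idx %/% side) %% side - side / 2),
        offset[3] + spacing * (idx %/% (side * side) - side / 2))
}
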