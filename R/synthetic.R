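#' Synthetic-data configuration
#'
#' Parameters of the toy genome and of the generators that emulate
#' proximity-ligation contact lists, ChIP-chip tracks and classified
#' replication-origin sets.  Defaults give a three-chromosome genome of
#' 350 / 280 / 175 kb (100 / 80 / 50 granules of 3.5 kb), interior
#' centromeres, terminal telomeres, and contact sets with power-law
#' distance decay plus planted centromere- and telomere-cluster pairs.
#'
#' @param chromLengths chromosome lengths in bp.
#' @param granuleBp bases per granule.
#' @param centromerePos relative centromere midpoint per chromosome.
#' @param centromereBp,telomereBp widths of the centromere interval and of
#'   each telomeric interval (bp).
#' @param nBackgroundPairs background distinct contact pairs.
#' @param intraFraction share of background pairs that are
#'   intra-chromosomal.
#' @param decayExponent power-law exponent of intra-chromosomal contact
#'   distance decay.
#' @param nCenPairs,nTelPairs planted centromere-centromere and
#'   telomere-telomere cluster pairs.
#' @param cenBoost,telBoost frequency up-weighting of the planted pairs
#'   (0 = no boost).
#' @param meanFreq,dispersion mean and negative-binomial size of the
#'   detection-frequency distribution (overdispersed counts >= 1).
#' @param nPeaks ChIP records per track.
#' @param peakBp ChIP probe length (bp; 300 bp probes).
#' @param chipBias probability that a ChIP record is placed in its
#'   compartment's zones (1 = fully compartmentalized, 0 = uniform).
#' @param zoneFlank pericentromeric flank (bp) included in the
#'   heterochromatic zones.
#' @param subtelomereBp subtelomeric zone width (bp) at each chromosome
#'   end.
#' @param originCounts named counts per origin class
#'   (timing_efficiency labels).
#' @param originBias probability that an origin is placed according to its
#'   class (early/high: euchromatic arms; late/low: subtelomeric).
#' @param seed default RNG seed for the generators.
#' @return named list of settings.
#' @export
syntheticConfig <- function(chromLengths = c(chrI = 350e3, chrII = 280e3,
                                             chrIII = 175e3),
                            granuleBp = 3500,
                            centromerePos = 0.4,
                            centromereBp = 10500,
                            telomereBp = 10500,
                            nBackgroundPairs = 760,
                            intraFraction = 1,
                            decayExponent = 1.0,
                            nCenPairs = 2,
                            nTelPairs = 2,
                            cenBoost = 2,
                            telBoost = 1,
                            meanFreq = 5,
                            dispersion = 2,
                            nPeaks = 1000,
                            peakBp = 300,
                            chipBias = 0.8,
                            zoneFlank = 20e3,
                            subtelomereBp = 30e3,
                            originCounts = c(early_high = 15, early_low = 10,
                                             late_high = 10, late_low = 15),
                            originBias = 0.9,
                            seed = 42) {
  stopifnot(all(chromLengths >= granuleBp), chipBias >= 0, chipBias <= 1,
            originBias >= 0, originBias <= 1, cenBoost >= 0, telBoost >= 0,
            nBackgroundPairs >= 0, nCenPairs >= 0, nTelPairs >= 0)
  cfg <- as.list(environment())
  cfg$centromerePos <- rep_len(centromerePos, length(chromLengths))
  cfg
}

#' Generate the toy genome
#'
#' @param cfg a [syntheticConfig()] list.
#' @return list of [ChromosomeSpec-class] objects.
#' @export
makeGenome <- function(cfg = syntheticConfig()) {
  lens <- cfg$chromLengths
  out <- vector("list", length(lens))
  for (c in seq_along(lens)) {
    L <- lens[[c]]
    mid <- round(cfg$centromerePos[c] * L)
    cen <- c(mid - cfg$centromereBp / 2, mid + cfg$centromereBp / 2)
    out[[c]] <- chromosomeSpec(
      names(lens)[c], L,
      centromere = round(cen),
      telomeres = list(c(0, cfg$telomereBp), c(L - cfg$telomereBp, L)))
  }
  out
}

# union of heterochromatin-favoured zones (pericentromere + subtelomeres),
# as a data.frame of 0-based half-open intervals
.hetZones <- function(genome, cfg) {
  rows <- list()
  for (ch in genome) {
    cen <- ch@centromere
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch@name,
      start = max(0, cen[1] - cfg$zoneFlank),
      end = min(ch@length, cen[2] + cfg$zoneFlank))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch@name, start = 0, end = cfg$subtelomereBp)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = ch@name, start = ch@length - cfg$subtelomereBp,
      end = ch@length)
  }
  do.call(rbind, rows)
}

.sampleInZones <- function(n, zones, width) {
  if (n == 0L) return(data.frame(chrom = character(), pos = numeric()))
  w <- pmax(zones$end - zones$start - width, 1)
  z <- sample.int(nrow(zones), n, replace = TRUE, prob = w)
  data.frame(chrom = zones$chrom[z],
             pos = floor(zones$start[z] + stats::runif(n) * w[z]))
}

.sampleOutsideZones <- function(n, genome, zones, width) {
  # rejection sampling against the zone union
  out <- data.frame(chrom = character(), pos = numeric())
  lens <- vapply(genome, function(c) c@length, numeric(1))
  names(lens) <- vapply(genome, function(c) c@name, character(1))
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 10
    chrom <- sample(names(lens), m, replace = TRUE, prob = lens)
    pos <- floor(stats::runif(m) * (lens[chrom] - width))
    inz <- rep(FALSE, m)
    for (z in seq_len(nrow(zones)))   # any overlap of [pos, pos + width)
      inz <- inz | (chrom == zones$chrom[z] & pos < zones$end[z] &
                      pos + width > zones$start[z])
    out <- rbind(out, data.frame(chrom = chrom[!inz], pos = pos[!inz]))
  }
  out[seq_len(n), ]
}

# overdispersed detection frequencies >= 1
.drawFreq <- function(n, cfg) {
  1 + stats::rnbinom(n, size = cfg$dispersion, mu = max(cfg$meanFreq - 1, 0))
}

#' Generate a synthetic contact list
#'
#' Emulates a population-level proximity-ligation pair list:
#' intra-chromosomal background pairs with power-law distance decay
#' (probability ~ distance^-decayExponent), a uniform low-rate
#' inter-chromosomal background, planted centromere-centromere and
#' telomere-telomere cluster pairs with up-weighted frequencies, and
#' overdispersed (negative-binomial) detection counts.
#'
#' @param genome list of [ChromosomeSpec-class] (from [makeGenome()]).
#' @param cfg a [syntheticConfig()] list.
#' @param seed RNG seed (default `cfg$seed`).
#' @return data.frame with columns chromA, posA, chromB, posB, count,
#'   ready for [writeContacts()] / [readContacts()].
#' @export
makeContacts <- function(genome, cfg = syntheticConfig(), seed = cfg$seed) {
  set.seed(seed)
  lens <- vapply(genome, function(c) c@length, numeric(1))
  names(lens) <- vapply(genome, function(c) c@name, character(1))
  ng <- sum(ceiling(lens / cfg$granuleBp))
  if (cfg$nBackgroundPairs + cfg$nCenPairs + cfg$nTelPairs >
      ng * (ng - 1) / 2)
    stop("more distinct pairs requested than granule pairs exist")

  nIntra <- round(cfg$nBackgroundPairs * cfg$intraFraction)
  nInter <- cfg$nBackgroundPairs - nIntra

  # intra: power-law distance decay; exponent 0 means uniform pairs
  # (independent endpoints), so flat-decay contacts are exchangeable
  intra <- NULL
  if (nIntra > 0) {
    chrom <- sample(names(lens), nIntra, replace = TRUE, prob = lens)
    dmin <- 2 * cfg$granuleBp
    a <- cfg$decayExponent
    if (a == 0) {
      posA <- posB <- numeric(nIntra)
      todo <- seq_len(nIntra)
      while (length(todo)) {     # rejection: endpoints >= dmin apart
        pa <- floor(stats::runif(length(todo)) * lens[chrom[todo]])
        pb <- floor(stats::runif(length(todo)) * lens[chrom[todo]])
        keep <- abs(pa - pb) >= dmin
        posA[todo[keep]] <- pa[keep]
        posB[todo[keep]] <- pb[keep]
        todo <- todo[!keep]
      }
    } else {
      u <- stats::runif(nIntra)
      dmax <- lens[chrom] - 1
      d <- if (abs(a - 1) < 1e-12) dmin * (dmax / dmin)^u
           else (dmin^(1 - a) + u * (dmax^(1 - a) - dmin^(1 - a)))^(1 / (1 - a))
      d <- pmin(floor(d), lens[chrom] - 2)
      posA <- floor(stats::runif(nIntra) * (lens[chrom] - d - 1))
      posB <- posA + d
    }
    intra <- data.frame(chromA = chrom, posA = posA, chromB = chrom,
                        posB = posB)
  }
  inter <- NULL
  if (nInter > 0) {
    cA <- sample(names(lens), nInter, replace = TRUE, prob = lens)
    cB <- vapply(cA, function(c) sample(setdiff(names(lens), c), 1), "")
    inter <- data.frame(chromA = cA,
                        posA = floor(stats::runif(nInter) * (lens[cA] - 1)),
                        chromB = cB,
                        posB = floor(stats::runif(nInter) * (lens[cB] - 1)))
  }
  # planted cluster pairs join zones on two *different* chromosomes
  # (centromere/telomere clustering is an inter-chromosomal signal)
  special <- function(nPairs, intervals, boost) {
    if (nPairs == 0L) return(NULL)
    if (length(unique(intervals$chrom)) < 2L)
      return(NULL)
    pickIn <- function(z) floor(intervals$start[z] +
                                  stats::runif(length(z)) *
                                  (intervals$end[z] - intervals$start[z] - 1))
    za <- sample.int(nrow(intervals), nPairs, replace = TRUE)
    zb <- vapply(za, function(z) {
      cand <- which(intervals$chrom != intervals$chrom[z])
      cand[sample.int(length(cand), 1)]
    }, integer(1))
    data.frame(chromA = intervals$chrom[za], posA = pickIn(za),
               chromB = intervals$chrom[zb], posB = pickIn(zb),
               count = ceiling(.drawFreq(nPairs, cfg) * (1 + boost)))
  }
  cens <- do.call(rbind, lapply(genome, function(ch) data.frame(
    chrom = ch@name, start = ch@centromere[1], end = ch@centromere[2])))
  tels <- do.call(rbind, lapply(genome, function(ch) do.call(rbind, lapply(
    ch@telomeres, function(t) data.frame(chrom = ch@name, start = t[1],
                                         end = t[2])))))
  bg <- rbind(intra, inter)
  bg$count <- .drawFreq(nrow(bg), cfg)
  out <- rbind(bg,
               special(cfg$nCenPairs, cens, cfg$cenBoost),
               special(cfg$nTelPairs, tels, cfg$telBoost))
  rownames(out) <- NULL
  out
}

#' Generate a compartment-biased synthetic ChIP track
#'
#' Probe-sized records (300 bp by default) with log-normal signals.  With
#' probability `chipBias` a record is placed in its compartment's zones:
#' pericentromeric/subtelomeric for `peripheral_het` (emulating
#' heterochromatic marks concentrated around centromeres and
#' subtelomeres), their complement for `central_eu` (marks spread over the
#' chromosome arms); otherwise placement is uniform.  Signal is
#' independent of position, so at bias 0 the top-signal records are
#' uniform over the genome.
#'
#' @param genome list of [ChromosomeSpec-class].
#' @param cfg a [syntheticConfig()] list.
#' @param compartment `"peripheral_het"` or `"central_eu"`.
#' @param seed RNG seed.
#' @return a `chip_signal` [FeatureTrack-class].
#' @export
makeChipTrack <- function(genome, cfg = syntheticConfig(),
                          compartment = c("peripheral_het", "central_eu"),
                          seed = cfg$seed) {
  compartment <- match.arg(compartment)
  set.seed(seed)
  zones <- .hetZones(genome, cfg)
  n <- cfg$nPeaks
  biased <- stats::runif(n) < cfg$chipBias
  nb <- sum(biased)
  placed <- if (compartment == "peripheral_het")
    .sampleInZones(nb, zones, cfg$peakBp)
  else .sampleOutsideZones(nb, genome, zones, cfg$peakBp)
  unif <- .sampleOutsideZones(n - nb, genome,
                              zones[0, , drop = FALSE], cfg$peakBp)
  pos <- rbind(placed, unif)
  featureTrack(compartment, pos$chrom, pos$pos, pos$pos + cfg$peakBp,
               score = stats::rlnorm(n), kind = "chip_signal")
}

#' Generate classified synthetic replication origins
#'
#' Origins are drawn per class from `cfg$originCounts`.  With probability
#' `originBias`, early-firing / high-efficiency origins are placed on the
#' euchromatic arms (outside pericentromeric/subtelomeric zones) and
#' late-firing / low-efficiency origins in subtelomeric zones; otherwise
#' placement is uniform.  Timing takes precedence when the two class axes
#' disagree (an `early_low` origin follows `early`).
#'
#' @param genome list of [ChromosomeSpec-class].
#' @param cfg a [syntheticConfig()] list.
#' @param seed RNG seed.
#' @param width origin interval width (bp).
#' @return data.frame in BED-6 layout: chrom, start, end, name, score,
#'   class.
#' @export
makeOrigins <- function(genome, cfg = syntheticConfig(), seed = cfg$seed,
                        width = 500) {
  set.seed(seed)
  zones <- .hetZones(genome, cfg)
  subtel <- do.call(rbind, lapply(genome, function(ch) data.frame(
    chrom = ch@name,
    start = c(0, ch@length - cfg$subtelomereBp),
    end = c(cfg$subtelomereBp, ch@length))))
  rows <- list()
  for (cls in names(cfg$originCounts)) {
    k <- cfg$originCounts[[cls]]
    if (k == 0) next
    timing <- strsplit(cls, "_")[[1]][1]
    biased <- stats::runif(k) < cfg$originBias
    nb <- sum(biased)
    placed <- if (timing == "early")
      .sampleOutsideZones(nb, genome, zones, width)
    else .sampleInZones(nb, subtel, width)
    unif <- .sampleOutsideZones(k - nb, genome, zones[0, , drop = FALSE],
                                width)
    pos <- rbind(placed, unif)
    rows[[cls]] <- data.frame(chrom = pos$chrom, start = pos$pos,
                              end = pos$pos + width,
                              name = paste0(cls, "_", seq_len(k)),
                              score = 0, class = cls)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a BED-like table
#'
#' @param df data.frame in BED column order.
#' @param path output file.
#' @export
writeBed <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' One-call synthetic model setup
#'
#' Convenience wrapper building the toy genome, its granule partition,
#' the default nuclear geometry and the Rabl anchor set (centromeres to
#' the SPB zone, telomeres to the periphery).
#'
#' @param cfg a [syntheticConfig()] list.
#' @param ... passed to [buildGeometry()].
#' @return list with `genome`, `partition`, `geometry`, `anchors`.
#' @export
syntheticSetup <- function(cfg = syntheticConfig(), ...) {
  genome <- makeGenome(cfg)
  partition <- buildPartition(genome, cfg$granuleBp)
  geometry <- buildGeometry(...)
  anchors <- rablAnchors(genome, partition)
  list(genome = genome, partition = partition, geometry = geometry,
       anchors = anchors)
}
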