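#' Describe one chromosome
#'
#' All coordinates are 0-based, half-open `[start, end)` base pairs.
#'
#' @param name chromosome name.
#' @param length chromosome length in bp (> 0).
#' @param centromere centromere interval `c(start, end)`, or `NULL`.
#' @param telomeres list of two intervals, one per chromosome end.
#' @param rdna optional list of rDNA intervals.
#' @return a [ChromosomeSpec-class].
#' @examples
#' chromosomeSpec("chrI", 35000, centromere = c(15000, 20000))
#' @export
chromosomeSpec <- function(name, length,
                           centromere = NULL,
                           telomeres = list(),
                           rdna = list()) {
  if (!is.numeric(length) || length(length) != 1L || length <= 0)
    stop("chromosome length must be a single positive number")
  new("ChromosomeSpec", name = as.character(name), length = as.numeric(length),
      centromere = if (is.null(centromere)) numeric() else as.numeric(centromere),
      telomeres = telomeres, rdna = rdna)
}

#' Partition chromosomes into granules
#'
#' Bins each chromosome into contiguous granules of `granuleBp` base pairs
#' (3.5 kb by default, so a 30 nm granule carries 3.5 kb of chromatin).
#' The last granule of a chromosome absorbs the remainder and may span
#' fewer bases.  Granule indices are global and consecutive in chromosome
#' order.
#'
#' @param chroms list of [ChromosomeSpec-class] objects (a single spec is
#'   accepted).
#' @param granuleBp bases per granule (> 0).
#' @return a [GranulePartition-class].
#' @examples
#' p <- buildPartition(chromosomeSpec("chrI", 35000), granuleBp = 3500)
#' nGranules(p)  # 10
#' @export
buildPartition <- function(chroms, granuleBp = 3500) {
  if (is(chroms, "ChromosomeSpec")) chroms <- list(chroms)
  if (!length(chroms)) stop("need at least one chromosome")
  if (!is.numeric(granuleBp) || granuleBp <= 0)
    stop("granuleBp must be > 0")
  lens <- vapply(chroms, function(c) c@length, numeric(1))
  if (any(lens <= 0)) stop("chromosome lengths must be > 0")
  names(lens) <- vapply(chroms, function(c) c@name, character(1))
  if (anyDuplicated(names(lens))) stop("duplicate chromosome names")

  starts0 <- ends0 <- numeric(0)
  chromv <- character(0)
  for (ch in chroms) {
    n <- ceiling(ch@length / granuleBp)
    s <- (seq_len(n) - 1) * granuleBp
    e <- pmin(s + granuleBp, ch@length)
    starts0 <- c(starts0, s)
    ends0 <- c(ends0, e)
    chromv <- c(chromv, rep(ch@name, n))
  }
  gr <- GenomicRanges::GRanges(chromv,
                               IRanges::IRanges(start = starts0 + 1, end = ends0))
  S4Vectors::mcols(gr)$granule <- seq_along(gr)
  new("GranulePartition", granules = gr, granuleBp = granuleBp,
      chromLengths = lens)
}

#' Map a base-pair position to its granule
#'
#' Returns the global index of the unique granule whose half-open interval
#' contains `pos`.  Vectorised over `chrom`/`pos`.
#'
#' @param partition a [GranulePartition-class].
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s) in bp, each in `[0, chromosome length)`.
#' @return integer granule index (1-based, global).
#' @examples
#' p <- buildPartition(chromosomeSpec("chrI", 35000))
#' bpToGranule(p, "chrI", c(0, 3499, 3500))  # 1 1 2
#' @export
bpToGranule <- function(partition, chrom, pos) {
  stopifnot(is(partition, "GranulePartition"))
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  lens <- partition@chromLengths
  unknown <- !(chrom %in% names(lens))
  if (any(unknown))
    stop("unknown chromosome: ", paste(unique(chrom[unknown]), collapse = ", "))
  if (any(pos < 0 | pos >= lens[chrom]))
    stop("position out of chromosome bounds")
  nper <- ceiling(lens / partition@granuleBp)
  offs <- c(0, cumsum(nper))[match(chrom, names(lens))]
  as.integer(offs + floor(pos / partition@granuleBp) + 1)
}

#' Build the nuclear geometry
#'
#' Places a spherical nucleus at the origin with the SPB on the envelope at
#' the `+z` pole and the nucleolus centred on the `-z` axis, so the
#' SPB-nucleolus axis is the rotational-projection axis.  Defaults give a
#' 1300 nm nuclear radius (half-radius 650 nm) and 30 nm granules.
#'
#' @param nuclearRadius nuclear radius in nm.
#' @param granuleDiameter granule diameter in nm.
#' @param nucleolusRadius nucleolar radius in nm (0 = no nucleolus).
#' @param nucleolusOffset distance of the nucleolus centre from the nuclear
#'   centre along the axis away from the SPB; defaults to
#'   `nuclearRadius - nucleolusRadius` (nucleolus touching the envelope at
#'   the pole opposite the SPB).
#' @param spbZoneRadius radius of the SPB anchor zone (nm).
#' @param peripheryWidth width of the peripheral anchor shell (nm).
#' @param nucleolarSurfaceWidth width of the nucleolar-surface shell (nm).
#' @return a [NuclearGeometry-class].
#' @examples
#' buildGeometry()
#' @export
buildGeometry <- function(nuclearRadius = 1300,
                          granuleDiameter = 30,
                          nucleolusRadius = 0,
                          nucleolusOffset = nuclearRadius - nucleolusRadius,
                          spbZoneRadius = 300,
                          peripheryWidth = 150,
                          nucleolarSurfaceWidth = 150) {
  if (nuclearRadius <= 0 || granuleDiameter <= 0 || nucleolusRadius < 0)
    stop("radii must be positive")
  if (nucleolusOffset + nucleolusRadius > nuclearRadius * (1 + 1e-9))
    stop("nucleolus protrudes outside the nucleus")
  new("NuclearGeometry",
      nuclearRadius = nuclearRadius,
      granuleDiameter = granuleDiameter,
      spbPosition = c(0, 0, nuclearRadius),
      nucleolusCenter = c(0, 0, -nucleolusOffset),
      nucleolusRadius = nucleolusRadius,
      axis = c(0, 0, 1),
      spbZoneRadius = spbZoneRadius,
      peripheryWidth = peripheryWidth,
      nucleolarSurfaceWidth = nucleolarSurfaceWidth)
}

#' Build an anchor set
#'
#' @param granule global granule indices to tether.
#' @param target region labels (`"SPB_zone"`, `"periphery"`,
#'   `"nucleolar_surface"`), recycled.
#' @param k spring constants (kT/nm^2), recycled.
#' @param partition optional [GranulePartition-class] used to validate
#'   indices.
#' @return an [AnchorSet-class].
#' @export
anchorSet <- function(granule = integer(), target = character(),
                      k = 0.05, partition = NULL) {
  granule <- as.integer(granule)
  n <- length(granule)
  target <- rep_len(as.character(target), n)
  k <- rep_len(as.numeric(k), n)
  if (!is.null(partition) && n &&
      any(granule < 1L | granule > nGranules(partition)))
    stop("anchored granule index outside the partition")
  new("AnchorSet", granule = granule, target = target, k = k)
}

#' Standard Rabl anchor set for a genome
#'
#' Tethers every centromere-overlapping granule to the SPB zone and every
#' telomere-overlapping granule to the nuclear periphery (or to the
#' nucleolar surface, as in rDNA-bearing chromosome ends, when
#' `telomereTarget = "nucleolar_surface"`).
#'
#' @param chroms list of [ChromosomeSpec-class].
#' @param partition matching [GranulePartition-class].
#' @param k spring constant (kT/nm^2).
#' @param telomereTarget region for telomeric granules.
#' @return an [AnchorSet-class].
#' @export
rablAnchors <- function(chroms, partition, k = 0.05,
                        telomereTarget = "periphery") {
  if (is(chroms, "ChromosomeSpec")) chroms <- list(chroms)
  g <- integer(); tg <- character()
  for (ch in chroms) {
    if (length(ch@centromere)) {
      idx <- .intervalGranules(partition, ch@name, ch@centromere)
      g <- c(g, idx); tg <- c(tg, rep("SPB_zone", length(idx)))
    }
    for (tel in ch@telomeres) {
      idx <- .intervalGranules(partition, ch@name, tel)
      g <- c(g, idx); tg <- c(tg, rep(telomereTarget, length(idx)))
    }
  }
  keep <- !duplicated(g)
  anchorSet(g[keep], tg[keep], k, partition)
}

# granules overlapping a 0-based half-open bp interval
.intervalGranules <- function(partition, chrom, iv) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(iv[1] + 1, iv[2]))
  hits <- GenomicRanges::findOverlaps(q, partition@granules)
  sort(unique(S4Vectors::subjectHits(hits)))
}
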