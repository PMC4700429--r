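#' @import methods
#' @importFrom GenomicRanges GRanges seqnames granges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols queryHits subjectHits
NULL

#' Chromosome description
#'
#' Holds the linear anatomy of one chromosome: its length and the
#' centromere, telomere and (optionally) rDNA intervals, all in 0-based
#' half-open base-pair coordinates.
#'
#' @slot name chromosome name.
#' @slot length chromosome length in bp.
#' @slot centromere numeric length-2 vector, centromere interval `[start, end)`.
#' @slot telomeres list of two length-2 vectors, one interval per chromosome end.
#' @slot rdna list of length-2 vectors (possibly empty), rDNA repeat intervals.
#' @export
setClass("ChromosomeSpec",
  slots = c(
    name = "character",
    length = "numeric",
    centromere = "numeric",
    telomeres = "list",
    rdna = "list"
  )
)

.validInterval <- function(x, len) {
  is.numeric(x) && length(x) == 2L && x[1] >= 0 && x[2] > x[1] && x[2] <= len
}

setValidity("ChromosomeSpec", function(object) {
  msg <- character()
  if (object@length <= 0) msg <- c(msg, "chromosome length must be > 0")
  if (length(object@centromere) &&
      !.validInterval(object@centromere, object@length))
    msg <- c(msg, "centromere interval out of bounds")
  for (tel in object@telomeres) {
    if (!.validInterval(tel, object@length))
      msg <- c(msg, "telomere interval out of bounds")
    if (length(object@centromere) &&
        object@centromere[1] < tel[2] && tel[1] < object@centromere[2])
      msg <- c(msg, "centromere overlaps a telomere")
  }
  if (length(msg)) msg else TRUE
})

#' Granule partition of a genome
#'
#' Fixed-size binning of chromosomes into polymer granules.  Each granule
#' represents `granuleBp` base pairs (default 3500); the last granule of a
#' chromosome may span less.  Granule indices are global, 1-based and
#' consecutive in chromosome order; the stored `GRanges` keeps the usual
#' 1-based closed convention while all user-facing bp arguments are 0-based
#' half-open.
#'
#' @slot granules `GRanges` of granule intervals with an `granule` index column.
#' @slot granuleBp bases per granule.
#' @slot chromLengths named integer-ish vector of chromosome lengths (bp).
#' @export
setClass("GranulePartition",
  slots = c(
    granules = "GRanges",
    granuleBp = "numeric",
    chromLengths = "numeric"
  )
)

setValidity("GranulePartition", function(object) {
  n <- length(object@granules)
  if (n == 0L) return("empty partition")
  if (!identical(S4Vectors::mcols(object@granules)$granule, seq_len(n)))
    return("granule indices must be 1..n in order")
  sp <- sum(GenomicRanges::width(object@granules))
  if (sp != sum(object@chromLengths))
    return("granule spans do not cover the chromosomes exactly")
  TRUE
})

#' Nuclear geometry
#'
#' The spherical nucleus of radius `nuclearRadius` centred at the origin,
#' with the spindle pole body (SPB) on the envelope at the `+axis` pole and
#' the nucleolus centred on the axis near the opposite pole.  `axis` is the
#' unit vector from the nuclear centre towards the SPB, so projections onto
#' it are positive on the SPB side.  Anchor target regions are parameterised
#' here: a spherical zone of radius `spbZoneRadius` around the SPB, a
#' peripheral shell of width `peripheryWidth` under the envelope, and a
#' shell of width `nucleolarSurfaceWidth` around the nucleolar surface.
#'
#' @slot nuclearRadius nuclear radius (nm).
#' @slot granuleDiameter granule diameter (nm).
#' @slot spbPosition xyz of the SPB on the envelope (nm).
#' @slot nucleolusCenter xyz of the nucleolus centre (nm).
#' @slot nucleolusRadius nucleolar radius (nm); 0 disables the exclusion.
#' @slot axis unit vector from nuclear centre towards the SPB.
#' @slot spbZoneRadius radius of the SPB anchor zone (nm).
#' @slot peripheryWidth width of the peripheral anchor shell (nm).
#' @slot nucleolarSurfaceWidth width of the nucleolar-surface anchor shell (nm).
#' @export
setClass("NuclearGeometry",
  slots = c(
    nuclearRadius = "numeric",
    granuleDiameter = "numeric",
    spbPosition = "numeric",
    nucleolusCenter = "numeric",
    nucleolusRadius = "numeric",
    axis = "numeric",
    spbZoneRadius = "numeric",
    peripheryWidth = "numeric",
    nucleolarSurfaceWidth = "numeric"
  )
)

setValidity("NuclearGeometry", function(object) {
  msg <- character()
  R <- object@nuclearRadius
  if (R <= 0) msg <- c(msg, "nuclearRadius must be > 0")
  if (object@granuleDiameter <= 0 || object@granuleDiameter >= R)
    msg <- c(msg, "granuleDiameter must be in (0, nuclearRadius)")
  if (abs(sqrt(sum(object@spbPosition^2)) - R) > 1e-9 * R)
    msg <- c(msg, "SPB must lie on the nuclear envelope")
  if (sqrt(sum(object@nucleolusCenter^2)) + object@nucleolusRadius > R + 1e-9 * R)
    msg <- c(msg, "nucleolus protrudes outside the nucleus")
  if (abs(sqrt(sum(object@axis^2)) - 1) > 1e-9)
    msg <- c(msg, "axis must be a unit vector")
  if (length(msg)) msg else TRUE
})

#' Anchor set
#'
#' Tethering restraints: granules attached to a named nuclear region
#' (`SPB_zone`, `periphery` or `nucleolar_surface`) by a flat-bottomed
#' harmonic well (zero energy inside the region, 1/2 k delta^2 outside,
#' delta the distance to the region).
#'
#' @slot granule global granule indices (1-based).
#' @slot target region label per anchor.
#' @slot k spring constant per anchor (kT/nm^2).
#' @export
setClass("AnchorSet",
  slots = c(granule = "integer", target = "character", k = "numeric")
)

setValidity("AnchorSet", function(object) {
  n <- length(object@granule)
  if (length(object@target) != n || length(object@k) != n)
    return("anchor slots must have equal length")
  if (n && !all(object@target %in% c("SPB_zone", "periphery", "nucleolar_surface")))
    return("unknown anchor target region")
  if (n && any(object@k <= 0)) return("anchor spring constants must be > 0")
  TRUE
})

#' Granule-level contact set
#'
#' Distinct non-adjacent granule pairs with summed detection frequencies,
#' aggregated from a bp-level proximity-ligation contact list.
#'
#' @slot i,j granule indices with `i < j`; pairs are unique and, when on the
#'   same chromosome, non-adjacent (`|i - j| > 1`).
#' @slot weight summed detection frequency per pair (>= 1).
#' @slot nGranules number of granules in the parent partition.
#' @export
setClass("GranuleContactSet",
  slots = c(i = "integer", j = "integer", weight = "numeric",
            nGranules = "integer")
)

setValidity("GranuleContactSet", function(object) {
  if (length(object@i) != length(object@j) ||
      length(object@i) != length(object@weight))
    return("i, j, weight must have equal length")
  if (length(object@i)) {
    if (any(object@i >= object@j)) return("pairs must satisfy i < j")
    if (any(object@weight < 1)) return("weights must be >= 1")
    if (anyDuplicated(paste(object@i, object@j))) return("duplicate pairs")
  }
  TRUE
})

#' Ensemble of genome conformations
#'
#' A set of independently optimized 3D conformations sharing one partition
#' and geometry.  `coords` is an `nGranules x 3 x nStructures` array of
#' granule centres (nm); each structure records its RNG seed and the index
#' of the contact subset it was restrained by.
#'
#' @slot coords numeric array, granules x xyz x structures.
#' @slot seeds integer seed per structure.
#' @slot subsets list of 2-column granule-pair matrices, one per structure.
#' @slot modelKind `"contact_restrained"` or `"random"`.
#' @slot partition the shared [GranulePartition-class].
#' @slot geometry the shared [NuclearGeometry-class].
#' @slot energies final total energy per structure.
#' @slot configHash hash of the generating configuration (provenance).
#' @export
setClass("GenomeEnsemble",
  slots = c(
    coords = "array",
    seeds = "integer",
    subsets = "list",
    modelKind = "character",
    partition = "GranulePartition",
    geometry = "NuclearGeometry",
    energies = "numeric",
    configHash = "character"
  )
)

setValidity("GenomeEnsemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L)
    return("coords must be an nGranules x 3 x nStructures array")
  if (length(object@seeds) != d[3]) return("one seed per structure required")
  if (anyDuplicated(object@seeds)) return("structure seeds must be distinct")
  if (!object@modelKind %in% c("contact_restrained", "random"))
    return("modelKind must be 'contact_restrained' or 'random'")
  TRUE
})

#' Per-granule feature signal
#'
#' One value per granule: binary presence/absence (`mode = "binary"`) or a
#' non-negative count (`mode = "count"`).
#'
#' @slot name track label.
#' @slot values numeric vector, one per granule.
#' @slot mode `"binary"` or `"count"`.
#' @export
setClass("GranuleSignal",
  slots = c(name = "character", values = "numeric", mode = "character")
)

setValidity("GranuleSignal", function(object) {
  if (!object@mode %in% c("binary", "count")) return("unknown signal mode")
  v <- object@values
  if (any(!is.finite(v))) return("signal values must be finite")
  if (object@mode == "binary" && !all(v %in% c(0, 1)))
    return("binary signals must be 0/1")
  if (object@mode == "count" && (any(v < 0) || any(v != floor(v))))
    return("count signals must be non-negative integers")
  TRUE
})

#' Linear feature track
#'
#' Interval records with a signal column, e.g. ChIP-chip probe enrichments
#' (`kind = "chip_signal"`) or point genetic elements such as replication
#' origins (`kind = "point_element"`).  Stored as a `GRanges` with a
#' `score` column.
#'
#' @slot name track label.
#' @slot records `GRanges` with numeric `score` metadata column.
#' @slot kind `"chip_signal"` or `"point_element"`.
#' @export
setClass("FeatureTrack",
  slots = c(name = "character", records = "GRanges", kind = "character")
)

setValidity("FeatureTrack", function(object) {
  if (!object@kind %in% c("chip_signal", "point_element"))
    return("unknown track kind")
  sc <- S4Vectors::mcols(object@records)$score
  if (length(object@records) && (is.null(sc) || any(!is.finite(sc))))
    return("records need a finite 'score' column")
  TRUE
})

#' Rotational-projection density grid
#'
#' Density of (weighted) granules on the (z, r) half-plane after rotational
#' projection about the SPB-nucleolus axis, evaluated with an isotropic 2D
#' Gaussian kernel at the centres of a 266 x 266 pixel grid covering
#' z in [-R, R] (rows) and r in [0, R] (columns).
#'
#' @slot values pixel raster (rows = z bins, cols = r bins).
#' @slot deltaZ,deltaR pixel size (nm) along z and r.
#' @slot sigma Gaussian kernel width (nm).
#' @slot nStructures number of structures averaged.
#' @slot nuclearRadius nuclear radius R defining the grid extent (nm).
#' @export
setClass("DensityGrid",
  slots = c(values = "matrix", deltaZ = "numeric", deltaR = "numeric",
            sigma = "numeric", nStructures = "integer",
            nuclearRadius = "numeric")
)

setValidity("DensityGrid", function(object) {
  if (any(!is.finite(object@values)) || any(object@values < 0))
    return("densities must be finite and >= 0")
  TRUE
})

#' Relative density map
#'
#' Element density divided by total chromatin density plus the Dempf
#' regularizer, pixel-wise on a congruent grid pair.
#'
#' @slot values raster of element / (total + Dempf).
#' @slot dempf the additive regularizer.
#' @slot deltaZ,deltaR,nuclearRadius grid geometry, as in [DensityGrid-class].
#' @export
setClass("RelativeDensityMap",
  slots = c(values = "matrix", dempf = "numeric", deltaZ = "numeric",
            deltaR = "numeric", nuclearRadius = "numeric")
)

#' Top-signal contour mask
#'
#' Boolean raster marking the highest-valued pixels of a relative density
#' map that jointly hold a configured fraction of its total signal.
#'
#' @slot mask logical raster.
#' @slot fraction requested signal fraction.
#' @slot enclosedFraction fraction actually enclosed (>= `fraction`, within
#'   one pixel's share).
#' @export
setClass("ContourMask",
  slots = c(mask = "matrix", fraction = "numeric",
            enclosedFraction = "numeric")
)

#' Per-granule impact profile
#'
#' Mean percentage density change contributed by each granule to a region
#' of interest (pixels within `regionRadius` of the rotation axis whose
#' aggregate change has the selected sign).
#'
#' @slot values mean % density change per granule.
#' @slot regionRadius radial cut-off (nm) defining the region of interest.
#' @slot pixelSign `"increased"` or `"decreased"`.
#' @slot nPixels number of selected pixels.
#' @export
setClass("ImpactProfile",
  slots = c(values = "numeric", regionRadius = "numeric",
            pixelSign = "character", nPixels = "integer")
)

#' Overlap report
#'
#' Counts and ratios quantifying co-localization of two binary signals
#' (granule counts) or two contour masks (pixel counts).
#'
#' @slot nA,nB,nIntersection set sizes and intersection size.
#' @slot jaccard intersection / union.
#' @slot minOverlap intersection / min(nA, nB).
#' @export
setClass("OverlapReport",
  slots = c(nA = "integer", nB = "integer", nIntersection = "integer",
            jaccard = "numeric", minOverlap = "numeric")
)

setValidity("OverlapReport", function(object) {
  if (object@nIntersection > min(object@nA, object@nB))
    return("intersection exceeds the smaller set")
  TRUE
})
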