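#' @rdname GranulePartition-class
#' @param x a `GranulePartition`.
#' @export
setGeneric("nGranules", function(x) standardGeneric("nGranules"))

#' @rdname GranulePartition-class
#' @export
setGeneric("granuleBp", function(x) standardGeneric("granuleBp"))

#' @rdname GranulePartition-class
#' @export
setGeneric("granuleRanges", function(x) standardGeneric("granuleRanges"))

#' @rdname GenomeEnsemble-class
#' @param x a `GenomeEnsemble`.
#' @export
setGeneric("nStructures", function(x) standardGeneric("nStructures"))

#' @rdname GenomeEnsemble-class
#' @param i structure index.
#' @export
setGeneric("structureCoords", function(x, i) standardGeneric("structureCoords"))

#' @rdname GranuleSignal-class
#' @param x a `GranuleSignal`.
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))

#' @rdname DensityGrid-class
#' @param x a grid-like object.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

setMethod("nGranules", "GranulePartition",
          function(x) length(x@granules))
setMethod("granuleBp", "GranulePartition", function(x) x@granuleBp)
setMethod("granuleRanges", "GranulePartition", function(x) x@granules)
setMethod("nGranules", "GenomeEnsemble",
          function(x) dim(x@coords)[1])
setMethod("nStructures", "GenomeEnsemble", function(x) dim(x@coords)[3])
setMethod("structureCoords", "GenomeEnsemble",
          function(x, i) matrix(x@coords[, , i], ncol = 3,
                                dimnames = list(NULL, c("x", "y", "z"))))
setMethod("signalValues", "GranuleSignal", function(x) x@values)
setMethod("gridValues", "DensityGrid", function(x) x@values)
setMethod("gridValues", "RelativeDensityMap", function(x) x@values)

setMethod("show", "GranulePartition", function(object) {
  cat("GranulePartition:", nGranules(object), "granules of",
      object@granuleBp, "bp over", length(object@chromLengths),
      "chromosome(s)\n")
})

setMethod("show", "NuclearGeometry", function(object) {
  cat(sprintf(
    "NuclearGeometry: R = %g nm, granule %g nm, nucleolus r = %g nm\n",
    object@nuclearRadius, object@granuleDiameter, object@nucleolusRadius))
})

setMethod("show", "GranuleContactSet", function(object) {
  cat("GranuleContactSet:", length(object@i), "distinct pairs, total weight",
      sum(object@weight), "\n")
})

setMethod("show", "GenomeEnsemble", function(object) {
  cat(sprintf("GenomeEnsemble (%s): %d structures x %d granules\n",
              object@modelKind, nStructures(object), nGranules(object)))
})

setMethod("show", "GranuleSignal", function(object) {
  cat(sprintf("GranuleSignal '%s' (%s): %d/%d granules flagged\n",
              object@name, object@mode, sum(object@values > 0),
              length(object@values)))
})

setMethod("show", "FeatureTrack", function(object) {
  cat(sprintf("FeatureTrack '%s' (%s): %d records\n",
              object@name, object@kind, length(object@records)))
})

setMethod("show", "DensityGrid", function(object) {
  cat(sprintf(
    "DensityGrid %dx%d, sigma %g nm, %d structure(s), total %.4g\n",
    nrow(object@values), ncol(object@values), object@sigma,
    object@nStructures, sum(object@values)))
})

setMethod("show", "RelativeDensityMap", function(object) {
  cat(sprintf("RelativeDensityMap %dx%d, Dempf %g, max %.4g\n",
              nrow(object@values), ncol(object@values), object@dempf,
              max(object@values)))
})

setMethod("show", "ContourMask", function(object) {
  cat(sprintf("ContourMask: %d pixels enclosing %.2f%% of signal (target %g%%)\n",
              sum(object@mask), 100 * object@enclosedFraction,
              100 * object@fraction))
})

setMethod("show", "OverlapReport", function(object) {
  cat(sprintf(
    "OverlapReport: |A| = %d, |B| = %d, |A&B| = %d, jaccard %.3f, min-overlap %.3f\n",
    object@nA, object@nB, object@nIntersection, object@jaccard,
    object@minOverlap))
})
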