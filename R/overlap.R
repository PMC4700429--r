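.overlapReport <- function(nA, nB, nI) {
  union <- nA + nB - nI
  new("OverlapReport", nA = as.integer(nA), nB = as.integer(nB),
      nIntersection = as.integer(nI),
      jaccard = if (union > 0) nI / union else 0,
      minOverlap = if (min(nA, nB) > 0) nI / min(nA, nB) else 0)
}

#' Linear (granule-level) overlap of two features
#'
#' Counts granules flagged by each binary signal and by both, the raw
#' material of a proportional-area Venn diagram of linear co-localization.
#'
#' @param a,b binary [GranuleSignal-class] objects on the same partition.
#' @return an [OverlapReport-class].
#' @export
linearOverlap <- function(a, b) {
  stopifnot(is(a, "GranuleSignal"), is(b, "GranuleSignal"))
  if (a@mode != "binary" || b@mode != "binary")
    stop("linear overlap requires binary signals")
  if (length(a@values) != length(b@values))
    stop("signals are on different partitions")
  .overlapReport(sum(a@values == 1), sum(b@values == 1),
                 sum(a@values == 1 & b@values == 1))
}

#' Spatial (contour-level) overlap of two features
#'
#' Pixel-count version of [linearOverlap()] for two contour masks.  Both
#' contours enclose the same signal fraction, so their Venn circles are
#' rendered equal-sized; the informative quantity is the intersection.
#'
#' @param a,b congruent [ContourMask-class] objects.
#' @return an [OverlapReport-class].
#' @export
spatialOverlap <- function(a, b) {
  stopifnot(is(a, "ContourMask"), is(b, "ContourMask"))
  if (!identical(dim(a@mask), dim(b@mask)))
    stop("masks are not congruent")
  .overlapReport(sum(a@mask), sum(b@mask), sum(a@mask & b@mask))
}

#' Directional coincidence of two contour masks
#'
#' Proportion of mask `a` lying inside mask `b`, `|A & B| / |A|` -- the
#' directional statistic behind statements like "feature X coincides with
#' region Y in >90% of its extent".  Not symmetric in its arguments.
#'
#' @param a,b congruent [ContourMask-class] objects; `a` must be
#'   non-empty.
#' @return proportion in [0, 1].
#' @export
coincidence <- function(a, b) {
  stopifnot(is(a, "ContourMask"), is(b, "ContourMask"))
  if (!identical(dim(a@mask), dim(b@mask)))
    stop("masks are not congruent")
  nA <- sum(a@mask)
  if (nA == 0L) stop("coincidence undefined for an empty mask")
  sum(a@mask & b@mask) / nA
}
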