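#' Construct a granule contact set
#'
#' Normalises granule pairs (swaps so `i < j`), merges duplicates by summing
#' weights, and drops self pairs and pairs adjacent on the same chromosome
#' (captured contacts are restricted to non-adjacent interactions; the
#' polymer backbone already connects neighbours).
#'
#' @param i,j granule indices.
#' @param weight detection frequency per pair (>= 1).
#' @param partition the [GranulePartition-class] the indices refer to.
#' @param verbose log the number of pairs kept/dropped.
#' @return a [GranuleContactSet-class].
#' @export
granuleContactSet <- function(i, j, weight, partition, verbose = FALSE) {
  stopifnot(is(partition, "GranulePartition"))
  i <- as.integer(i); j <- as.integer(j); weight <- as.numeric(weight)
  stopifnot(length(i) == length(j), length(i) == length(weight))
  n <- nGranules(partition)
  if (length(i) && (any(i < 1L | i > n) || any(j < 1L | j > n)))
    stop("granule index outside the partition")
  lo <- pmin(i, j); hi <- pmax(i, j)
  self <- lo == hi
  chrom <- as.character(GenomicRanges::seqnames(partition@granules))
  adjacent <- !self & (hi - lo == 1L) & chrom[lo] == chrom[hi]
  keep <- !self & !adjacent
  if (verbose)
    message(sprintf("contacts: %d records kept, %d self, %d adjacent dropped",
                    sum(keep), sum(self), sum(adjacent)))
  lo <- lo[keep]; hi <- hi[keep]; weight <- weight[keep]
  if (length(lo)) {
    key <- paste(lo, hi)
    agg <- rowsum(weight, key)
    ord <- match(rownames(agg), key)
    lo <- lo[ord]; hi <- hi[ord]; weight <- as.numeric(agg)
    o <- order(lo, hi)
    lo <- lo[o]; hi <- hi[o]; weight <- weight[o]
  }
  new("GranuleContactSet", i = lo, j = hi, weight = weight,
      nGranules = as.integer(n))
}

#' Read a proximity-ligation contact list
#'
#' Parses a tab-separated pair list
#' (`chromA<TAB>posA<TAB>chromB<TAB>posB<TAB>count`, '#' comments and an
#' optional header ignored), maps both ends to granules and aggregates
#' into a [GranuleContactSet-class]; same-granule and backbone-adjacent
#' pairs are dropped and duplicates merged.
#'
#' @param path TSV file path (or a data.frame already holding the five
#'   columns).
#' @param partition a [GranulePartition-class].
#' @param verbose log kept/dropped counts.
#' @return a [GranuleContactSet-class].
#' @export
readContacts <- function(path, partition, verbose = TRUE) {
  if (is.data.frame(path)) {
    df <- path
    if (ncol(df) < 5) stop("contact table needs 5 columns")
    df <- df[, 1:5]
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    if (length(lines) && grepl("^chrom", lines[1], ignore.case = TRUE))
      lines <- lines[-1]
    if (!length(lines)) stop("no contact records in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 5L)
    if (length(bad))
      stop(sprintf("malformed contact line %d in %s", bad[1], path))
    df <- data.frame(
      chromA = vapply(parts, `[`, "", 1L),
      posA = as.numeric(vapply(parts, `[`, "", 2L)),
      chromB = vapply(parts, `[`, "", 3L),
      posB = as.numeric(vapply(parts, `[`, "", 4L)),
      count = as.numeric(vapply(parts, `[`, "", 5L)))
    if (anyNA(df$posA) || anyNA(df$posB) || anyNA(df$count))
      stop("non-numeric coordinate or count in ", path)
  }
  names(df) <- c("chromA", "posA", "chromB", "posB", "count")
  if (any(df$count < 1)) stop("contact frequencies must be >= 1")
  gi <- bpToGranule(partition, df$chromA, df$posA)
  gj <- bpToGranule(partition, df$chromB, df$posB)
  granuleContactSet(gi, gj, df$count, partition, verbose = verbose)
}

#' Write a contact list as TSV
#'
#' @param records data.frame with columns chromA, posA, chromB, posB, count.
#' @param path output file.
#' @export
writeContacts <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Draw one frequency-proportional contact subset
#'
#' Samples `round(fraction * total)` distinct pairs without replacement,
#' each draw proportional to the pair's summed detection frequency
#' (successive draws with renormalisation).  This mirrors how a single
#' cell realises only a subset of the population-averaged contacts, with
#' frequent contacts more likely to be present.
#'
#' @param set a [GranuleContactSet-class].
#' @param fraction proportion of distinct pairs per structure (0, 1].
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return integer matrix with columns `i`, `j`.
#' @export
sampleSubset <- function(set, fraction, seed = NULL) {
  stopifnot(is(set, "GranuleContactSet"))
  total <- length(set@i)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  k <- round(fraction * total)
  if (k < 1) stop("fraction * total < 1: no pairs to draw")
  if (!is.null(seed)) set.seed(seed)
  idx <- if (k == total) seq_len(total)
         else sample.int(total, k, replace = FALSE, prob = set@weight)
  cbind(i = set@i[idx], j = set@j[idx])
}

#' Assign contact subsets to an ensemble of structures
#'
#' Each structure receives an independent [sampleSubset()] draw; afterwards
#' any pair never selected is appended round-robin across structures so
#' that every captured interaction is present in at least one model.
#'
#' @param set a [GranuleContactSet-class].
#' @param fraction subset fraction per structure.
#' @param nStructures number of structures (>= 1).
#' @param seed integer seed for the whole assignment.
#' @param verbose log the number of force-assigned pairs.
#' @return list of `nStructures` two-column pair matrices.
#' @export
assignSubsets <- function(set, fraction, nStructures, seed = NULL,
                          verbose = TRUE) {
  stopifnot(nStructures >= 1)
  if (!is.null(seed)) set.seed(seed)
  subsets <- lapply(seq_len(nStructures), function(s)
    sampleSubset(set, fraction, seed = NULL))
  key <- function(m) paste(m[, 1], m[, 2])
  all_keys <- paste(set@i, set@j)
  seen <- unique(unlist(lapply(subsets, key)))
  missing <- which(!(all_keys %in% seen))
  if (length(missing)) {
    if (verbose)
      message(sprintf("assignSubsets: force-assigning %d uncovered pair(s)",
                      length(missing)))
    tgt <- rep_len(seq_len(nStructures), length(missing))
    for (m in seq_along(missing)) {
      s <- tgt[m]
      subsets[[s]] <- rbind(subsets[[s]],
                            c(set@i[missing[m]], set@j[missing[m]]))
    }
  }
  subsets
}

#' Calibrate the contact-subset fraction against a target Rg
#'
#' Bisection over the subset fraction: for each candidate a small
#' calibration ensemble is generated and its mean radius of gyration
#' compared to `targetRg`.  More contacts compact the genome, so Rg is
#' (stochastically) decreasing in the fraction; the bracket is checked and
#' a violation reported.  Returns the fraction whose calibration-ensemble
#' mean Rg falls within `tol` (relative) of the target.
#'
#' @param set a [GranuleContactSet-class].
#' @param targetRg target mean radius of gyration (nm); must be smaller
#'   than the nuclear radius.
#' @param partition,geometry model setup passed to [generateEnsemble()].
#' @param anchors tethers used during calibration.  The default (none)
#'   calibrates contact count against the confinement-only polymer, so the
#'   bracket runs from the random-model Rg down to the fully restrained
#'   one and the calibration isolates the contact-driven compaction.
#' @param params [energyParams()] list.
#' @param nCalib calibration ensemble size (default 20 structures).
#' @param tol relative Rg tolerance (default 0.05).
#' @param seed master seed.
#' @param maxIter bisection iteration cap.
#' @param lower,upper initial fraction bracket.
#' @param verbose log each bisection step.
#' @return list with `fraction`, `meanRg`, `ensemble` (the calibration
#'   ensemble at the returned fraction) and the bisection `trace`.
#' @export
calibrateFraction <- function(set, targetRg, partition, geometry,
                              anchors = anchorSet(),
                              params = energyParams(geometry),
                              nCalib = 20, tol = 0.05, seed = 1,
                              maxIter = 12, lower = 0.01, upper = 1,
                              verbose = TRUE) {
  stopifnot(is(set, "GranuleContactSet"))
  if (targetRg >= geometry@nuclearRadius)
    stop("targetRg must be below the nuclear radius")
  evalRg <- function(frac, s) {
    ens <- generateEnsemble(nCalib, partition, geometry, anchors, set,
                            fraction = frac, params = params,
                            masterSeed = s, verbose = FALSE)
    mean(apply(ens@coords, 3, radiusOfGyration))
  }
  trace <- data.frame(fraction = numeric(), meanRg = numeric())
  note <- function(f, rg) {
    trace[nrow(trace) + 1L, ] <<- c(f, rg)
    if (verbose) message(sprintf("calibrate: fraction %.4f -> mean Rg %.1f nm",
                                 f, rg))
    rg
  }
  rgLo <- note(lower, evalRg(lower, seed + 101L))
  if (abs(rgLo - targetRg) <= tol * targetRg)
    return(list(fraction = lower, meanRg = rgLo,
                ensemble = generateEnsemble(nCalib, partition, geometry,
                                            anchors, set, fraction = lower,
                                            params = params,
                                            masterSeed = seed + 101L,
                                            verbose = FALSE),
                trace = trace))
  rgHi <- note(upper, evalRg(upper, seed + 102L))
  if (rgLo < rgHi)
    warning("Rg not decreasing in fraction on the bracket; ",
            "monotonicity assumption violated")
  if (targetRg > rgLo || targetRg < rgHi)
    stop(sprintf(
      "calibration failure: target %.0f nm outside bracket [%.1f, %.1f] nm",
      targetRg, rgHi, rgLo))
  lo <- lower; hi <- upper
  for (it in seq_len(maxIter)) {
    mid <- sqrt(lo * hi)  # geometric midpoint: Rg responds ~log(fraction)
    s <- seed + 200L + it
    rgMid <- note(mid, evalRg(mid, s))
    if (abs(rgMid - targetRg) <= tol * targetRg) {
      ens <- generateEnsemble(nCalib, partition, geometry, anchors, set,
                              fraction = mid, params = params,
                              masterSeed = s, verbose = FALSE)
      return(list(fraction = mid, meanRg = rgMid, ensemble = ens,
                  trace = trace))
    }
    if (rgMid > targetRg) lo <- mid else hi <- mid
  }
  stop(sprintf(
    "calibration did not converge in %d iterations; bracket Rg [%.1f, %.1f]",
    maxIter, min(trace$meanRg), max(trace$meanRg)))
}
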