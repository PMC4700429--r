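#' Build a feature track
#'
#' @param name track label.
#' @param chrom,start,end 0-based half-open intervals in bp (BED
#'   convention, so BED rows pass straight through).
#' @param score numeric signal per record (ChIP enrichment; 0 for point
#'   elements without a value).
#' @param kind `"chip_signal"` or `"point_element"`.
#' @return a [FeatureTrack-class].
#' @export
featureTrack <- function(name, chrom, start, end, score = 0,
                         kind = c("chip_signal", "point_element")) {
  kind <- match.arg(kind)
  n <- length(chrom)
  score <- rep_len(as.numeric(score), n)
  gr <- GenomicRanges::GRanges(as.character(chrom),
                               IRanges::IRanges(start = as.numeric(start) + 1,
                                                end = as.numeric(end)))
  S4Vectors::mcols(gr)$score <- score
  new("FeatureTrack", name = as.character(name), records = gr, kind = kind)
}

#' Read a BED track
#'
#' Reads a 5-column BED (`chrom start end name score`); fewer columns are
#' padded (`score` defaults to 0).  BED is 0-based half-open, matching the
#' package convention, so coordinates pass through unshifted.
#'
#' @param path BED file.
#' @param name track label (default: file name).
#' @param kind track kind.
#' @return a [FeatureTrack-class].
#' @export
readBedTrack <- function(path, name = basename(path),
                         kind = c("chip_signal", "point_element")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "class")[1:.bedNcol(path)],
                          stringsAsFactors = FALSE)
  score <- if ("score" %in% names(df)) df$score else 0
  featureTrack(name, df$chrom, df$start, df$end, score, kind)
}

.bedNcol <- function(path) {
  first <- utils::read.table(path, sep = "\t", header = FALSE, nrows = 1,
                             comment.char = "#")
  min(ncol(first), 6L)
}

#' Keep the top fraction of ChIP records
#'
#' Retains the `ceiling(fraction * N)` records with the highest signal
#' (the analysis restricts ChIP tracks to the top 5% of signals by
#' default, so low-enrichment probes do not blur the spatial maps).  Ties
#' at the threshold are broken by genomic order (chromosome, then start),
#' keeping exactly `ceiling(fraction * N)` records.
#'
#' @param track a `chip_signal` [FeatureTrack-class].
#' @param fraction proportion to keep, in (0, 1].
#' @return a filtered [FeatureTrack-class], records in genomic order.
#' @export
topFractionFilter <- function(track, fraction = 0.05) {
  stopifnot(is(track, "FeatureTrack"))
  if (track@kind != "chip_signal")
    stop("top-fraction filtering applies to chip_signal tracks")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- length(track@records)
  if (n == 0L) {
    warning("empty track: nothing to filter")
    return(track)
  }
  k <- ceiling(fraction * n)
  gr <- track@records
  chromf <- as.integer(GenomicRanges::seqnames(gr))
  ord <- order(-S4Vectors::mcols(gr)$score, chromf,
               GenomicRanges::start(gr))
  keep <- sort(ord[seq_len(k)])
  new("FeatureTrack", name = track@name, records = gr[keep],
      kind = track@kind)
}

# overlap hits between track records and granules, with bounds checking
.trackHits <- function(track, partition) {
  gr <- track@records
  lens <- partition@chromLengths
  chrom <- as.character(GenomicRanges::seqnames(gr))
  if (any(!(chrom %in% names(lens))))
    stop("record on unknown chromosome")
  if (any(GenomicRanges::end(gr) > lens[chrom]) ||
      any(GenomicRanges::start(gr) < 1))
    stop("record extends past the end of its chromosome")
  GenomicRanges::findOverlaps(gr, partition@granules)
}

#' Binary granule mapping
#'
#' Marks every granule overlapped by at least one record (any overlap,
#' including partial) with 1, all others 0.
#'
#' @param track a [FeatureTrack-class].
#' @param partition a [GranulePartition-class].
#' @return a binary [GranuleSignal-class].
#' @export
mapBinary <- function(track, partition) {
  hits <- .trackHits(track, partition)
  v <- numeric(nGranules(partition))
  v[unique(S4Vectors::subjectHits(hits))] <- 1
  new("GranuleSignal", name = track@name, values = v, mode = "binary")
}

#' Count granule mapping
#'
#' Counts, per granule, the records whose midpoint falls inside it
#' (midpoint assignment keeps counts additive over the partition; with
#' 300 bp probes the count measures the extent of the enriched region
#' within the 3.5 kb granule).
#'
#' @inheritParams mapBinary
#' @return a count-mode [GranuleSignal-class].
#' @export
mapCounts <- function(track, partition) {
  .trackHits(track, partition)  # bounds check
  gr <- track@records
  v <- numeric(nGranules(partition))
  if (length(gr)) {
    # 0-based midpoint of the half-open interval, assigned half-open
    mid0 <- floor((GenomicRanges::start(gr) - 1 +
                     GenomicRanges::end(gr)) / 2)
    g <- bpToGranule(partition,
                     as.character(GenomicRanges::seqnames(gr)), mid0)
    tab <- tabulate(g, nbins = nGranules(partition))
    v <- as.numeric(tab)
  }
  new("GranuleSignal", name = track@name, values = v, mode = "count")
}

#' Load classified replication origins
#'
#' Reads a BED-like file whose 6th column carries the origin class --
#' firing-time and/or efficiency labels drawn from `early`, `late`,
#' `high`, `medium`, `low`, combined with `_` (e.g. `early_high`) -- and
#' returns one binary granule signal per distinct class value.  Duplicate
#' origin lines flag a granule once.
#'
#' @param path origin BED file (chrom, start, end, name, score, class).
#' @param partition a [GranulePartition-class].
#' @return named list of binary [GranuleSignal-class] objects.
#' @export
loadOrigins <- function(path, partition) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 6L) stop("origin file needs 6 columns (class in column 6)")
  names(df)[1:6] <- c("chrom", "start", "end", "name", "score", "class")
  allowed <- c("early", "late", "high", "medium", "low")
  toks <- strsplit(df$class, "[_:,/]")
  bad <- !vapply(toks, function(t) all(t %in% allowed), logical(1))
  if (any(bad))
    stop("unknown origin class label: ", df$class[which(bad)[1]])
  out <- list()
  for (cls in unique(df$class)) {
    sub <- df[df$class == cls, , drop = FALSE]
    tr <- featureTrack(cls, sub$chrom, sub$start, sub$end, sub$score,
                       kind = "point_element")
    out[[cls]] <- mapBinary(tr, partition)
  }
  out
}

#' Export a granule signal as TSV
#'
#' @param signal a [GranuleSignal-class].
#' @param path output file (columns: granule, value).
#' @export
writeSignalTSV <- function(signal, path) {
  utils::write.table(
    data.frame(granule = seq_along(signal@values), value = signal@values),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
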