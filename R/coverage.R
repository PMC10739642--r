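## Binned coverage tracks, RPKM normalisation and the m6A signal.
##
## The per-bin statistic is the fragment-overlap count: the number of
## fragments with at least one block overlapping the bin (each fragment
## counted once per bin, however many of its blocks touch it). RPKM follows
## RPKM_b = count_b / (binWidth/1000 * totalFragments/1e6).

#' Bin fragment coverage over the genome
#'
#' Counts, for every fixed-width bin, the fragments whose exonic blocks
#' overlap the bin, and optionally normalises to RPKM using the set's total
#' fragment count.
#'
#' @param frags a [FragmentSet-class].
#' @param binWidth bin width in bp (default 10).
#' @param normalize `"rpkm"` (default) or `"count"`.
#' @return a [BinnedTrack-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(31, 175),
#'   seqinfo = GenomeInfoDb::Seqinfo("chr1", 1000))
#' fs <- fragmentSet(gr)
#' trackValues(binCoverage(fs, normalize = "count"))$chr1  # bins 3..17 hit
#' @export
binCoverage <- function(frags, binWidth = 10L, normalize = c("rpkm", "count")) {
  normalize <- match.arg(normalize)
  binWidth <- as.integer(binWidth)
  if (binWidth <= 0L) stop("binWidth must be > 0", call. = FALSE)
  si <- seqinfo(frags)
  vals <- emptyBins(si, binWidth)
  gr <- fragments(frags)
  total <- length(gr)
  if (total) {
    bl <- mcols(gr)$blocks
    nb <- lengths(bl)
    fragIdx <- rep.int(seq_along(gr), nb)
    flat <- unlist(bl, use.names = FALSE)
    bs0 <- start(gr)[fragIdx] - 1L + start(flat) - 1L   # 0-based block start
    be0 <- bs0 + width(flat)                            # half-open end
    chrom <- as.character(seqnames(gr))[fragIdx]
    ib <- intervalBins(bs0, be0, binWidth)
    ## one count per (fragment, bin) pair even if two blocks share a bin
    nBinsTot <- max(vapply(vals, length, 0L))
    key <- (fragIdx[ib$interval] - 1) * as.double(nBinsTot + 1L) + ib$bin
    keep <- !duplicated(key)
    chromHit <- chrom[ib$interval][keep]
    binHit <- ib$bin[keep]
    for (ch in unique(chromHit)) {
      t <- tabulate(binHit[chromHit == ch] + 1L, nbins = length(vals[[ch]]))
      vals[[ch]] <- vals[[ch]] + t
    }
  }
  if (normalize == "rpkm" && total > 0)
    vals <- lapply(vals, function(v) v / (binWidth / 1000 * total / 1e6))
  new("BinnedTrack", binWidth = binWidth, values = vals, seqinfo = si,
      totalFragments = as.numeric(total),
      kind = if (normalize == "rpkm") "rpkm" else "count")
}

#' The m6A signal track
#'
#' Per-bin m6A signal `s_b = log2((IP RPKM_b + 1) / (input RPKM_b + 1))`,
#' finite everywhere.
#'
#' @param ip,inp RPKM [BinnedTrack-class]s on the same bin grid.
#' @param ipId,inputId sample ids recorded on the result.
#' @return a [SignalTrack-class].
#' @export
m6aSignal <- function(ip, inp, ipId = "IP", inputId = "input") {
  if (ip@binWidth != inp@binWidth ||
      !identical(seqlengths(ip@seqinfo), seqlengths(inp@seqinfo)))
    stop("IP and input tracks are on different bin grids", call. = FALSE)
  if (ip@kind != "rpkm" || inp@kind != "rpkm")
    stop("m6aSignal expects RPKM tracks", call. = FALSE)
  vals <- lapply(names(ip@values), function(ch)
    log2((ip@values[[ch]] + 1) / (inp@values[[ch]] + 1)))
  names(vals) <- names(ip@values)
  new("SignalTrack", binWidth = ip@binWidth, values = vals,
      seqinfo = ip@seqinfo, totalFragments = ip@totalFragments,
      kind = "signal", ipId = ipId, inputId = inputId)
}

#' Exonic bin mask
#'
#' Bins (0-based indices per chromosome) overlapping the union of exons of
#' all annotated transcripts -- the "exonic region" restriction used by the
#' correlation and PCA summaries.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param binWidth bin width in bp.
#' @return named list of sorted 0-based bin index vectors.
#' @export
exonicBins <- function(annotation, binWidth = 10L) {
  ex <- reduce(unlist(annotation@exonsByTx), ignore.strand = TRUE)
  out <- lapply(stats::setNames(nm = seqlevels(annotation@seqinfo)),
                function(ch) integer())
  if (!length(ex)) return(out)
  ib <- intervalBins(start(ex) - 1L, end(ex), binWidth)
  chrom <- as.character(seqnames(ex))[ib$interval]
  for (ch in unique(chrom))
    out[[ch]] <- sort(unique(ib$bin[chrom == ch]))
  out
}

## Aggregate per-bin track values to larger windows over exonic bins only:
## window value = mean of its exonic bin values. Returns one numeric vector
## concatenated across chromosomes (same layout for every track on the grid),
## NA for windows without exonic bins.
aggregateWindows <- function(track, annotation, window = 1000L) {
  bw <- track@binWidth
  perWin <- as.integer(window %/% bw)
  mask <- exonicBins(annotation, bw)
  out <- list()
  for (ch in names(track@values)) {
    v <- track@values[[ch]]
    keep <- mask[[ch]]
    win <- keep %/% perWin
    if (!length(keep)) next
    sums <- tapply(v[keep + 1L], win, mean)
    nWin <- ceiling(length(v) / perWin)
    full <- rep(NA_real_, nWin)
    full[as.integer(names(sums)) + 1L] <- as.numeric(sums)
    out[[ch]] <- full
  }
  unlist(out, use.names = FALSE)
}

#' Pairwise transcriptome-wide correlation of tracks
#'
#' Re-aggregates each track to `window`-sized means over exonic bins and
#' computes the Pearson correlation per pair. Windows with no exonic bins,
#' and windows with zero value in all samples, are dropped before
#' correlating. A zero-variance track yields NA against every partner.
#'
#' @param tracks list of [BinnedTrack-class]s on one genome/grid.
#' @param annotation the [GenomeAnnotation-class] providing the exonic mask.
#' @param window aggregation window in bp (default 1000).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwiseCorrelation <- function(tracks, annotation, window = 1000L) {
  if (length(tracks) < 2L) stop("need at least two tracks", call. = FALSE)
  m <- vapply(tracks, aggregateWindows, numeric(length(
    aggregateWindows(tracks[[1]], annotation, window))),
    annotation = annotation, window = window)
  keep <- rowSums(is.na(m)) == 0 & rowSums(m != 0) > 0
  m <- m[keep, , drop = FALSE]
  r <- suppressWarnings(stats::cor(m, method = "pearson"))
  diag(r) <- 1
  nm <- names(tracks)
  if (!is.null(nm)) dimnames(r) <- list(nm, nm)
  r
}

#' PCA of m6A signal tracks
#'
#' Aggregates each signal track to `window`-sized exonic means, drops
#' all-NA/all-zero windows, centres features and takes the top two singular
#' directions. Signs are fixed so the largest-magnitude loading of each
#' component is positive, making coordinates deterministic.
#'
#' @param signalTracks named list of at least three [SignalTrack-class]s.
#' @param annotation the [GenomeAnnotation-class].
#' @param window aggregation window in bp.
#' @return list with `coords` (samples x PC1/PC2) and `varianceExplained`
#'   (length-2 fractions).
#' @export
pcaM6A <- function(signalTracks, annotation, window = 1000L) {
  if (length(signalTracks) < 3L)
    stop("PCA needs at least three samples", call. = FALSE)
  m <- vapply(signalTracks, aggregateWindows, numeric(length(
    aggregateWindows(signalTracks[[1]], annotation, window))),
    annotation = annotation, window = window)
  keep <- rowSums(is.na(m)) == 0 & rowSums(m != 0) > 0
  m <- t(m[keep, , drop = FALSE])          # samples x windows
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$rotation))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) coords[, j] <- -coords[, j]
  }
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(coords = coords, varianceExplained = ve)
}
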