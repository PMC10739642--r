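## Retrotransposon-derived RNA methylation: locus filtering, per-locus
## expression/m6A signal, subfamily methylated fractions and
## consensus-coordinate profiles.

#' Filter retrotransposon loci
#'
#' Keeps a locus iff (1) its length is at least 90% of the subfamily's
#' full-length consensus and (2) strictly less than 50% of its bases
#' overlap exons of annotated (non-retro) genes. Idempotent and independent
#' of input order.
#'
#' @param loci `GRanges` with `subfamily` and `consensusLength` columns
#'   (e.g. `retroLoci(annotation)` or [readRetroTSV()]).
#' @param annotation a [GenomeAnnotation-class] supplying the exon union.
#' @return the retained subset of `loci`.
#' @export
filterRetroLoci <- function(loci, annotation) {
  if (!length(loci)) return(loci)
  if (any(mcols(loci)$consensusLength <= 0))
    stop("consensusLength must be > 0", call. = FALSE)
  tx <- annotation@transcripts
  geneTx <- mcols(tx)$txId[mcols(tx)$txType != "retro"]
  ex <- reduce(unstrand(unlist(annotation@exonsByTx[geneTx])))
  lenOK <- width(loci) >= 0.9 * mcols(loci)$consensusLength
  ovBases <- rep(0, length(loci))
  h <- findOverlaps(loci, ex, ignore.strand = TRUE)
  if (length(h)) {
    w <- width(GenomicRanges::pintersect(
      GenomicRanges::granges(loci)[S4Vectors::queryHits(h)],
      ex[S4Vectors::subjectHits(h)], ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(h), sum)
    ovBases[as.integer(names(agg))] <- agg
  }
  loci[lenOK & (ovBases / width(loci) < 0.5)]
}

## per-locus mean of a track's bins overlapping the locus
lociBinMeans <- function(loci, track) {
  bw <- track@binWidth
  vapply(seq_along(loci), function(i) {
    ch <- as.character(seqnames(loci))[i]
    b0 <- binIndex(start(loci)[i] - 1L, bw)
    b1 <- binIndex(end(loci)[i] - 1L, bw)
    mean(track@values[[ch]][(b0:b1) + 1L])
  }, 0)
}

#' Per-locus expression and m6A signal
#'
#' Expression of a locus is the mean input RPKM across the 10-bp bins
#' overlapping it; its m6A signal is the mean [m6aSignal()] value across
#' the same bins. Multiple replicate tracks are averaged arithmetically
#' per locus.
#'
#' @param loci retained retro `GRanges` (see [filterRetroLoci()]).
#' @param inputTracks list of input RPKM [BinnedTrack-class]s (replicates).
#' @param signalTracks list of [SignalTrack-class]s (replicates).
#' @return data.frame(locusId, subfamily, expression, m6aSignal).
#' @export
retroLocusStats <- function(loci, inputTracks, signalTracks) {
  if (!is.list(inputTracks)) inputTracks <- list(inputTracks)
  if (!is.list(signalTracks)) signalTracks <- list(signalTracks)
  expr <- rowMeans(matrix(vapply(inputTracks, lociBinMeans,
                                 numeric(length(loci)), loci = loci),
                          nrow = length(loci)))
  sig <- rowMeans(matrix(vapply(signalTracks, lociBinMeans,
                                numeric(length(loci)), loci = loci),
                         nrow = length(loci)))
  data.frame(locusId = mcols(loci)$locusId, subfamily = mcols(loci)$subfamily,
             expression = expr, m6aSignal = sig, row.names = NULL)
}

#' Methylated fraction per retrotransposon subfamily
#'
#' For each subfamily, the fraction of retained loci with m6A signal
#' strictly greater than zero (any positive log2 IP/input ratio).
#'
#' @param locusStats a [retroLocusStats()] table (optionally with an extra
#'   `condition` column for cross-condition tables).
#' @return data.frame(subfamily \[, condition\], nLoci, fractionMethylated).
#' @export
subfamilyFractions <- function(locusStats) {
  by <- if ("condition" %in% names(locusStats))
    list(subfamily = locusStats$subfamily,
         condition = locusStats$condition)
  else list(subfamily = locusStats$subfamily)
  agg <- stats::aggregate(locusStats$m6aSignal, by = by,
                          FUN = function(v) c(n = length(v),
                                              frac = mean(v > 0)))
  out <- data.frame(agg[, -ncol(agg), drop = FALSE],
                    nLoci = agg$x[, "n"],
                    fractionMethylated = agg$x[, "frac"])
  out[order(out$subfamily), , drop = FALSE]
}

#' Profile a subfamily in consensus coordinates
#'
#' Maps each genomic bin of every locus proportionally onto the subfamily
#' consensus (position fraction times consensus length; minus-strand loci
#' reversed) and averages the track values per consensus bin across loci.
#' An affine approximation to alignment-based consensus coordinates.
#'
#' @param loci loci of one subfamily (`GRanges` with `consensusLength`).
#' @param track a [BinnedTrack-class] or [SignalTrack-class].
#' @return data.frame(consensusBin \[0-based\], value, nLoci).
#' @export
consensusProfile <- function(loci, track) {
  if (!length(loci)) stop("no loci to profile", call. = FALSE)
  consLen <- mcols(loci)$consensusLength[1]
  bw <- track@binWidth
  nCons <- as.integer(ceiling(consLen / bw))
  sums <- counts <- numeric(nCons)
  for (i in seq_along(loci)) {
    ch <- as.character(seqnames(loci))[i]
    s0 <- start(loci)[i] - 1L; e0 <- end(loci)[i]
    b0 <- binIndex(s0, bw); b1 <- binIndex(e0 - 1L, bw)
    v <- track@values[[ch]][(b0:b1) + 1L]
    mid <- (pmax(b0:b1 * bw, s0) + pmin((b0:b1 + 1L) * bw, e0)) / 2
    frac <- (mid - s0) / (e0 - s0)
    if (as.character(strand(loci))[i] == "-") frac <- 1 - frac
    cb <- pmin(nCons - 1L, as.integer(floor(frac * consLen / bw)))
    for (j in seq_along(cb)) {
      sums[cb[j] + 1L] <- sums[cb[j] + 1L] + v[j]
      counts[cb[j] + 1L] <- counts[cb[j] + 1L] + 1
    }
  }
  data.frame(consensusBin = seq_len(nCons) - 1L,
             value = ifelse(counts > 0, sums / counts, NA_real_),
             nLoci = length(loci))
}
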