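## Replicate overlap, downsampling saturation, q-value robustness sweep and
## spike-in false-discovery assessment.

#' Fraction of query peaks overlapping a reference set
#'
#' Fraction of query peaks sharing at least 1 bp with any reference peak
#' (asymmetric by design); `summitInPeak = TRUE` instead requires the query
#' summit to fall inside a reference peak.
#'
#' @param query,reference peak `GRanges`.
#' @param summitInPeak use summit-in-peak instead of 1-bp interval overlap.
#' @return fraction in \[0, 1\], or `NA` for an empty query.
#' @export
overlapFraction <- function(query, reference, summitInPeak = FALSE) {
  if (!length(query)) return(NA_real_)
  q <- if (summitInPeak) summitPositions(query) else query
  mean(GenomicRanges::countOverlaps(q, reference, ignore.strand = TRUE) > 0)
}

## subsample a FragmentSet without replacement
subsampleFragments <- function(frags, fraction, seed, stream) {
  if (fraction >= 1) return(frags)
  n <- length(frags)
  k <- floor(fraction * n)
  if (k < 1) stop("subsample of < 1 fragment", call. = FALSE)
  withSubstream(seed, stream, {
    idx <- sort(sample.int(n, k))
    out <- frags
    out@fragments <- fragments(frags)[idx]
    out
  })
}

#' Downsampling saturation of peak detection
#'
#' Subsamples the IP and input libraries without replacement to each
#' fraction (per seed), re-calls peaks with the identical configuration and
#' tabulates the peak counts. Fraction 1.0 reproduces the full-data call
#' exactly.
#'
#' @param ip,inp [FragmentSet-class]s.
#' @param fractions subsampling fractions in (0, 1].
#' @param nSeeds subsampling repetitions per fraction.
#' @param cfg a [PeakCallerConfig-class].
#' @param seed base seed for the subsampling streams.
#' @return data.frame(fraction, seed, nPeaks).
#' @export
downsampleSaturation <- function(ip, inp, fractions = c(0.1, 0.25, 0.5, 1),
                                 nSeeds = 5L, cfg = peakCallerConfig(),
                                 seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must be in (0, 1]", call. = FALSE)
  out <- list()
  fullPeaks <- NULL
  for (f in fractions) {
    for (s in seq_len(nSeeds)) {
      if (f >= 1) {
        if (is.null(fullPeaks))
          fullPeaks <- callPeaks(deduplicate(ip), deduplicate(inp), cfg)
        np <- length(fullPeaks)
      } else {
        ipS <- subsampleFragments(ip, f, seed,
                                  sprintf("downsample/ip/%g/%d", f, s))
        inpS <- subsampleFragments(inp, f, seed,
                                   sprintf("downsample/input/%g/%d", f, s))
        np <- length(callPeaks(deduplicate(ipS), deduplicate(inpS), cfg))
      }
      out[[length(out) + 1L]] <- data.frame(fraction = f, seed = s,
                                            nPeaks = np)
    }
  }
  do.call(rbind, out)
}

#' q-value robustness sweep
#'
#' Calls peaks once at the loosest cutoff, then derives every stricter row
#' by filtering that call on the peak q-value (a single BH pass, no
#' re-ranking). Each row reports the peak count, the RRACH fraction, the
#' fraction of peaks at the stop codon or 3'UTR, the fraction replicated in
#' a second replicate's call (filtered in parallel), and the fraction
#' overlapping an optional reference peak set.
#'
#' @param ip,inp replicate-1 IP/input [FragmentSet-class]s.
#' @param ip2,inp2 replicate-2 libraries (or NULL to skip `fracReplicated`).
#' @param genome,annotation,tpm context for motif/feature statistics.
#' @param referencePeaks optional reference `GRanges`.
#' @param cutoffs decreasing q cutoffs; the first (loosest) defines the
#'   single peak call.
#' @param cfg a [PeakCallerConfig-class]; its `qCutoff` is overridden by
#'   the loosest cutoff.
#' @return data.frame, one row per cutoff: qCutoff, nPeaks, fracRrach,
#'   fracStop3utr, fracReplicated, fracVsReference.
#' @export
qvalueSweep <- function(ip, inp, ip2 = NULL, inp2 = NULL, genome,
                        annotation, tpm = NULL, referencePeaks = NULL,
                        cutoffs = c(0.05, 1e-5, 1e-20, 1e-50, 1e-100),
                        cfg = peakCallerConfig()) {
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  cfg@qCutoff <- cutoffs[1]
  peaks <- callPeaks(ip, inp, cfg)
  peaks2 <- if (!is.null(ip2)) callPeaks(ip2, inp2, cfg) else NULL
  rows <- list()
  for (cut in cutoffs) {
    pk <- peaks[mcols(peaks)$q < cut]
    row <- data.frame(qCutoff = cut, nPeaks = length(pk),
                      fracRrach = NA_real_, fracStop3utr = NA_real_,
                      fracReplicated = NA_real_,
                      fracVsReference = NA_real_)
    if (length(pk)) {
      st <- deduceStrand(pk, annotation, tpm)
      keep <- !is.na(st)
      if (any(keep))
        row$fracRrach <- mean(scanRRACH(pk[keep], genome,
                                        st[keep])$hasMotif)
      asg <- assignFeature(pk, annotation)
      row$fracStop3utr <- mean(asg$feature %in% c("stop_codon", "utr3"))
      if (!is.null(peaks2))
        row$fracReplicated <-
          overlapFraction(pk, peaks2[mcols(peaks2)$q < cut])
      if (!is.null(referencePeaks))
        row$fracVsReference <- overlapFraction(pk, referencePeaks)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Motif and 3'-end statistics for shared versus replicate-unique peaks
#'
#' Partitions replicate-1 peaks into those sharing at least 1 bp with a
#' replicate-2 peak (shared) and the rest (unique), and reports the RRACH
#' fraction and the stop-codon/3'UTR fraction for each class.
#'
#' @param peaks1,peaks2 peak `GRanges` of the two replicates.
#' @param genome,annotation,tpm context for the statistics.
#' @return data.frame with one row per class (`shared`, `unique`).
#' @export
sharedVsUnique <- function(peaks1, peaks2, genome, annotation, tpm = NULL) {
  shared <- GenomicRanges::countOverlaps(peaks1, peaks2,
                                         ignore.strand = TRUE) > 0
  stat <- function(pk) {
    if (!length(pk))
      return(c(n = 0, fracRrach = NA_real_, fracStop3utr = NA_real_))
    st <- deduceStrand(pk, annotation, tpm)
    keep <- !is.na(st)
    fr <- if (any(keep))
      mean(scanRRACH(pk[keep], genome, st[keep])$hasMotif) else NA_real_
    asg <- assignFeature(pk, annotation)
    c(n = length(pk), fracRrach = fr,
      fracStop3utr = mean(asg$feature %in% c("stop_codon", "utr3")))
  }
  res <- rbind(stat(peaks1[shared]), stat(peaks1[!shared]))
  data.frame(class = c("shared", "unique"), res, row.names = NULL)
}

#' Spike-in false-discovery counts
#'
#' Peak counts on the spike-in contigs, keyed by their truth status: a
#' specific IP should peak on the modified contig and not on the unmodified
#' one.
#'
#' @param peaks peak `GRanges`.
#' @param spikeinStatus named logical (contig -> modified), e.g.
#'   `truth@spikeinStatus`.
#' @return list with `nPeaksModified`, `nPeaksUnmodified` and the per-contig
#'   table `perContig`.
#' @export
spikeinFdr <- function(peaks, spikeinStatus) {
  if (!length(spikeinStatus))
    stop("no spike-in contigs in the truth registry", call. = FALSE)
  cnt <- vapply(names(spikeinStatus), function(sn)
    sum(as.character(seqnames(peaks)) == sn), 0)
  list(nPeaksModified = sum(cnt[spikeinStatus]),
       nPeaksUnmodified = sum(cnt[!spikeinStatus]),
       perContig = data.frame(contig = names(spikeinStatus),
                              modified = unname(spikeinStatus),
                              nPeaks = unname(cnt)))
}

#' Score peak calls against the planted truth
#'
#' Recall is the fraction of scored planted sites with a peak summit within
#' `tolerance` bp; precision is the fraction of peaks whose summit lies
#' within `tolerance` bp of any planted site (of any kind -- a peak on a
#' methylated retro locus is a true discovery). Recall is scored on the
#' condition's gene sites and the spike-in sites by default; retro loci
#' carry sites whose detectability depends on locus expression, so they are
#' excluded from the recall denominator unless requested.
#'
#' @param peaks peak `GRanges` with `summit` column.
#' @param truth a [SyntheticTruth-class].
#' @param condition which condition's gene sites to score.
#' @param tolerance bp (default 200).
#' @param recallKinds site kinds in the recall denominator.
#' @return list(recall, precision, nPeaks, nSites).
#' @export
scorePeaks <- function(peaks, truth, condition = 1L, tolerance = 200L,
                       recallKinds = c("gene", "spikein")) {
  s <- truth@sites
  keep <- (mcols(s)$kind != "gene") |
    (!is.na(mcols(s)$condition) & mcols(s)$condition == condition)
  s <- s[keep]
  sRec <- s[mcols(s)$kind %in% recallKinds]
  if (!length(s) || !length(peaks))
    return(list(recall = if (length(sRec)) 0 else NA_real_,
                precision = if (length(peaks)) 0 else NA_real_,
                nPeaks = length(peaks), nSites = length(sRec)))
  sm <- summitPositions(peaks)
  win <- GRanges(seqnames(sm),
                 IRanges(pmax(1L, start(sm) - tolerance),
                         start(sm) + tolerance),
                 seqinfo = seqinfo(sm))
  hit <- GenomicRanges::countOverlaps(unstrand(GenomicRanges::granges(sRec)),
                                      win, ignore.strand = TRUE) > 0
  near <- GenomicRanges::countOverlaps(win,
                                       unstrand(GenomicRanges::granges(s)),
                                       ignore.strand = TRUE) > 0
  list(recall = mean(hit), precision = mean(near),
       nPeaks = length(peaks), nSites = length(sRec))
}
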