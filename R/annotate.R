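## Priority-ordered peak-to-feature assignment, m6A gene calling, the
## observed/expected feature enrichment score, and metagene profiles.

FEATURE_ORDER <- c("stop_codon", "utr3", "utr5", "cds", "exon", "intron",
                   "intergenic")

## Feature GRanges (with geneId) per class, in priority order. The
## stop-codon class is the +/-200 bp genomic window around the annotated
## stop codon; exon catches any transcript exon (including non-coding
## spike-in/retro transcripts); intron is transcript span minus exons.
featureRegions <- function(annotation) {
  tx <- annotation@transcripts
  txGene <- stats::setNames(mcols(tx)$geneId, mcols(tx)$txId)
  grlWithGene <- function(grl) {
    gr <- unlist(grl)
    if (!length(gr)) {
      mcols(gr)$geneId <- character()
      return(gr)
    }
    mcols(gr) <- DataFrame(geneId = txGene[rep(names(grl), lengths(grl))])
    gr
  }
  sc <- annotation@stopCodons
  stopWin <- GRanges(seqnames(sc),
                     IRanges(pmax(1L, start(sc) - 200L),
                             pmin(seqlengths(annotation@seqinfo)[
                               as.character(seqnames(sc))],
                               end(sc) + 200L)),
                     seqinfo = annotation@seqinfo)
  mcols(stopWin) <- DataFrame(geneId = txGene[names(sc)])

  exon <- grlWithGene(annotation@exonsByTx)
  spans <- GRanges(seqnames(tx), IRanges(start(tx), end(tx)),
                   seqinfo = annotation@seqinfo)
  mcols(spans) <- DataFrame(geneId = mcols(tx)$geneId)
  ## introns: per transcript, span minus exons
  intronList <- GenomicRanges::psetdiff(
    GenomicRanges::granges(tx) |> unstrand(),
    lapply(mcols(tx)$txId, function(id)
      unstrand(annotation@exonsByTx[[id]])) |> GRangesList())
  intron <- unlist(intronList)
  mcols(intron) <- DataFrame(geneId = mcols(tx)$geneId[
    rep(seq_along(tx), lengths(intronList))])

  list(stop_codon = stopWin,
       utr3 = grlWithGene(annotation@utr3ByTx),
       utr5 = grlWithGene(annotation@utr5ByTx),
       cds = grlWithGene(annotation@cdsByTx),
       exon = exon,
       intron = intron)
}

unstrand <- function(gr) {
  strand(gr) <- "*"
  gr
}

#' Assign each peak summit one genomic feature
#'
#' Summits are tested against the feature classes in priority order --
#' stop codon (the +/-200 bp genomic window around the annotated stop
#' codon), 3'UTR, 5'UTR, CDS, exon, intron, intergenic -- and the first hit
#' wins, so every peak receives exactly one feature. Multiple genes in the
#' same class are resolved to the lexicographically first gene id.
#'
#' @param peaks peak `GRanges` (with `summit` column) from [callPeaks()].
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame(name, feature, geneId) with `feature` a factor in
#'   priority order and `geneId` NA for intergenic peaks.
#' @export
assignFeature <- function(peaks, annotation) {
  n <- length(peaks)
  feature <- rep("intergenic", n)
  geneId <- rep(NA_character_, n)
  if (n) {
    sm <- summitPositions(peaks)
    regions <- featureRegions(annotation)
    unassigned <- rep(TRUE, n)
    for (f in names(regions)) {
      gr <- regions[[f]]
      if (!length(gr)) next
      h <- findOverlaps(sm, gr, ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(h)
      ok <- unassigned[qh]
      if (!any(ok)) next
      qh <- qh[ok]; sh <- S4Vectors::subjectHits(h)[ok]
      o <- order(qh, mcols(gr)$geneId[sh])
      first <- !duplicated(qh[o])
      idx <- qh[o][first]
      feature[idx] <- f
      geneId[idx] <- mcols(gr)$geneId[sh[o][first]]
      unassigned[idx] <- FALSE
    }
  }
  nm <- if ("name" %in% colnames(mcols(peaks)) && n) mcols(peaks)$name
        else as.character(seq_len(n))
  data.frame(name = nm, feature = factor(feature, levels = FEATURE_ORDER),
             geneId = geneId)
}

#' Call m6A-marked genes
#'
#' A gene is m6A-marked when any of its genomic features overlaps at least
#' one peak summit. With `requireBothReplicates = TRUE` the call is the
#' intersection over replicates, and intron hits no longer qualify
#' (the replicate-supported definition covers stop codon, UTRs, CDS and
#' exon only).
#'
#' @param assignments an [assignFeature()] table, or a list of them (one
#'   per replicate).
#' @param requireBothReplicates require the gene in every replicate.
#' @return sorted character vector of gene ids.
#' @export
m6aGenes <- function(assignments, requireBothReplicates = FALSE) {
  if (is.data.frame(assignments)) assignments <- list(assignments)
  if (requireBothReplicates && length(assignments) < 2L)
    stop("requireBothReplicates needs at least two replicates",
         call. = FALSE)
  markFeatures <- c("stop_codon", "utr3", "utr5", "cds", "exon",
                    if (!requireBothReplicates) "intron")
  sets <- lapply(assignments, function(a)
    unique(a$geneId[a$feature %in% markFeatures & !is.na(a$geneId)]))
  if (requireBothReplicates) sort(Reduce(intersect, sets))
  else sort(unique(unlist(sets)))
}

#' Observed/expected feature enrichment scores
#'
#' Expected counts are proportional to the priority-masked genomic length
#' of each feature class (each base counted once, under the same priority
#' order used by [assignFeature()]); the score is
#' `log2(observed / expected)`, `-Inf` when a feature has no observed
#' peaks.
#'
#' @param assignments an [assignFeature()] table.
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame(feature, observed, expected, score).
#' @export
featureEnrichment <- function(assignments, annotation) {
  total <- nrow(assignments)
  if (total == 0L) stop("no peaks to score", call. = FALSE)
  regions <- featureRegions(annotation)
  G <- sum(as.numeric(seqlengths(annotation@seqinfo)))
  lens <- numeric(length(FEATURE_ORDER))
  names(lens) <- FEATURE_ORDER
  acc <- GRanges(seqinfo = annotation@seqinfo)
  for (f in names(regions)) {
    gr <- reduce(unstrand(GenomicRanges::granges(regions[[f]])))
    masked <- GenomicRanges::setdiff(gr, acc)
    lens[f] <- sum(as.numeric(width(masked)))
    acc <- reduce(c(acc, gr))
  }
  lens["intergenic"] <- G - sum(lens[names(regions)])
  observed <- as.numeric(table(assignments$feature)[FEATURE_ORDER])
  observed[is.na(observed)] <- 0
  expected <- total * lens / G
  score <- ifelse(observed > 0, log2(observed / expected), -Inf)
  data.frame(feature = FEATURE_ORDER, observed = observed,
             expected = unname(expected), score = unname(score),
             row.names = NULL)
}

## genomic (1-based) position -> 0-based transcript coordinate, NA if the
## position does not fall in an exon of the transcript.
genomicToTx <- function(pos, tab) {
  gEnd0 <- tab$gStart0 + tab$width
  i <- which(pos - 1 >= tab$gStart0 & pos - 1 < gEnd0)
  if (!length(i)) return(NA_integer_)
  i <- i[1]
  if (tab$strand == "+") tab$txStart0[i] + (pos - 1 - tab$gStart0[i])
  else tab$txStart0[i] + (gEnd0[i] - pos)
}

#' Metagene profile of peak summits
#'
#' Maps each summit to its host gene's highest-TPM isoform (ties broken by
#' longer transcript, then id), positions it fractionally within the
#' 5'UTR/CDS/3'UTR, and rescales the three segments to unit length:
#' metagene coordinate in \[0,1) is 5'UTR, \[1,2) CDS, \[2,3\] 3'UTR (the
#' CDS/3'UTR boundary -- the stop codon -- sits at 2.0). Summits outside
#' the exons of the selected isoform are dropped and counted.
#'
#' @param peaks peak `GRanges` with `summit` column.
#' @param annotation a [GenomeAnnotation-class].
#' @param tpm a [transcriptTPM()] table.
#' @param binsPerSegment histogram bins per segment (default 30).
#' @return list with `coords` (one metagene coordinate per mapped summit),
#'   `density` data.frame(mid, density) normalised to unit area over
#'   \[0,3\], and `nDropped`.
#' @export
metagene <- function(peaks, annotation, tpm, binsPerSegment = 30L) {
  tx <- annotation@transcripts
  coding <- which(mcols(tx)$txType == "gene" & !is.na(mcols(tx)$u5Len) &
                  mcols(tx)$u5Len > 0 & mcols(tx)$cdsLen > 0 &
                  mcols(tx)$u3Len > 0)
  if (!length(coding)) stop("no complete protein-coding transcripts",
                            call. = FALSE)
  cd <- data.frame(idx = coding,
                   txId = mcols(tx)$txId[coding],
                   geneId = mcols(tx)$geneId[coding],
                   txLen = mcols(tx)$txLen[coding])
  cd$TPM <- tpm$TPM[match(cd$txId, tpm$txId)]
  cd$TPM[is.na(cd$TPM)] <- 0
  o <- order(cd$geneId, -cd$TPM, -cd$txLen, cd$txId)
  sel <- cd[o, ][!duplicated(cd$geneId[o]), ]

  selSpan <- GenomicRanges::granges(tx)[sel$idx]
  sm <- summitPositions(peaks)
  h <- findOverlaps(sm, selSpan, ignore.strand = TRUE)
  coords <- numeric(0)
  nDropped <- length(peaks)
  if (length(h)) {
    qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
    o <- order(qh, -sel$TPM[sh], sel$txId[sh])
    first <- !duplicated(qh[o])
    qs <- qh[o][first]; ss <- sh[o][first]
    for (j in seq_along(qs)) {
      i <- sel$idx[ss[j]]
      tab <- txExonTable(annotation, mcols(tx)$txId[i])
      tp <- genomicToTx(start(sm)[qs[j]], tab)
      if (is.na(tp)) next
      u5 <- mcols(tx)$u5Len[i]; cds <- mcols(tx)$cdsLen[i]
      u3 <- mcols(tx)$u3Len[i]
      coords <- c(coords, if (tp < u5) tp / u5
                  else if (tp < u5 + cds) 1 + (tp - u5) / cds
                  else 2 + (tp - u5 - cds) / u3)
    }
    nDropped <- length(peaks) - length(coords)
  }
  breaks <- seq(0, 3, by = 1 / binsPerSegment)
  hst <- if (length(coords))
    graphics::hist(coords, breaks = breaks, plot = FALSE)
  else list(mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
            density = rep(0, length(breaks) - 1L))
  list(coords = coords,
       density = data.frame(mid = hst$mids, density = hst$density),
       nDropped = nDropped)
}
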