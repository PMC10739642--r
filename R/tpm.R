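#' Transcript abundance (TPM) from input fragments
#'
#' Assigns each fragment to the transcript whose span contains the
#' fragment's genomic midpoint (ties between overlapping transcripts broken
#' by longest overlap with the fragment span, then lexicographic transcript
#' id), then converts counts to transcripts per million:
#' `rate_t = count_t / exonic_kb_t`, `TPM_t = 1e6 * rate_t / sum(rates)`.
#'
#' @param inputFrags a [FragmentSet-class] (an input library).
#' @param annotation a [GenomeAnnotation-class].
#' @return data.frame(txId, geneId, exonicLength, count, TPM); TPM sums to
#'   1e6 whenever any fragment is assigned, and is all-zero for an empty
#'   library.
#' @importFrom GenomicRanges findOverlaps pintersect
#' @export
transcriptTPM <- function(inputFrags, annotation) {
  tx <- annotation@transcripts
  ids <- mcols(tx)$txId
  exLen <- vapply(ids, function(id)
    sum(width(annotation@exonsByTx[[id]])), 0)
  gr <- fragments(inputFrags)
  counts <- stats::setNames(numeric(length(ids)), ids)
  if (length(gr)) {
    mid0 <- (start(gr) - 1L) + (width(gr) - 1L) %/% 2L
    mids <- GRanges(seqnames(gr), IRanges(mid0 + 1L, width = 1L),
                    seqinfo = seqinfo(gr))
    h <- findOverlaps(mids, tx, ignore.strand = TRUE)
    if (length(h)) {
      qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
      ov <- width(pintersect(GenomicRanges::granges(gr)[qh],
                             GenomicRanges::granges(tx)[sh],
                             ignore.strand = TRUE))
      ## per fragment: keep largest overlap, then lexicographically first id
      o <- order(qh, -ov, ids[sh])
      qo <- qh[o]
      first <- !duplicated(qo)
      t <- table(ids[sh[o][first]])
      counts[names(t)] <- as.numeric(t)
    }
  }
  rate <- ifelse(exLen > 0, counts / (exLen / 1000), 0)
  tpm <- if (sum(rate) > 0) 1e6 * rate / sum(rate) else rate
  data.frame(txId = ids, geneId = mcols(tx)$geneId,
             exonicLength = unname(exLen), count = unname(counts),
             TPM = unname(tpm), row.names = NULL)
}
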