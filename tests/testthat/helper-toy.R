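# Hand-built annotation with exactly known coordinates, for boundary tests.
#
# chrT (20 kb):
#   txA/geneA "+": single exon [1001,1600]; u5 100, cds 300, u3 200;
#                  stop codon [1398,1400]
#   txB/geneB "-": single exon [1201,1800]; same segment lengths;
#                  stop codon [1401,1403]
#   txC/geneC "+": exons [5001,5300]+[5701,6200] (intron [5301,5700]);
#                  u5 100, cds 300, u3 400; stop codon [5798,5800]

toyAnnotation <- function() {
  si <- GenomeInfoDb::Seqinfo("chrT", 20000L)
  gr <- function(s, e, strand) {
    if (!length(s)) return(GenomicRanges::GRanges(seqinfo = si))
    GenomicRanges::GRanges("chrT", IRanges::IRanges(s, e), strand = strand,
                           seqinfo = si)
  }
  tx <- c(gr(1001, 1600, "+"), gr(1201, 1800, "-"),
          gr(5001, 6200, "+"))
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    txId = c("txA", "txB", "txC"),
    geneId = c("geneA", "geneB", "geneC"),
    txType = "gene", txLen = c(600L, 600L, 800L), u5Len = 100L,
    cdsLen = 300L, u3Len = c(200L, 200L, 400L))

  exons <- GenomicRanges::GRangesList(
    txA = gr(1001, 1600, "+"),
    txB = gr(1201, 1800, "-"),
    txC = c(gr(5001, 5300, "+"), gr(5701, 6200, "+")))
  # transcript-coordinate features mapped by hand
  u5 <- GenomicRanges::GRangesList(
    txA = gr(1001, 1100, "+"), txB = gr(1701, 1800, "-"),
    txC = gr(5001, 5100, "+"))
  cds <- GenomicRanges::GRangesList(
    txA = gr(1101, 1400, "+"), txB = gr(1401, 1700, "-"),
    txC = c(gr(5101, 5300, "+"), gr(5701, 5800, "+")))
  u3 <- GenomicRanges::GRangesList(
    txA = gr(1401, 1600, "+"), txB = gr(1201, 1400, "-"),
    txC = gr(5801, 6200, "+"))
  stopC <- c(gr(1398, 1400, "+"), gr(1401, 1403, "-"), gr(5798, 5800, "+"))
  names(stopC) <- c("txA", "txB", "txC")

  retro <- gr(integer(0), integer(0), character(0))
  S4Vectors::mcols(retro) <- S4Vectors::DataFrame(
    locusId = character(), subfamily = character(),
    consensusLength = integer())

  new("GenomeAnnotation", seqinfo = si, transcripts = tx, exonsByTx = exons,
      cdsByTx = cds, utr5ByTx = u5, utr3ByTx = u3, stopCodons = stopC,
      retroLoci = retro)
}

toyTpm <- function(tpmA = 50, tpmB = 5, tpmC = 10) {
  data.frame(txId = c("txA", "txB", "txC"), TPM = c(tpmA, tpmB, tpmC))
}

# width-1 peak GRanges with explicit summits on chrT
toyPeaks <- function(summits) {
  gr <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(summits, width = 1L),
                               seqinfo = GenomeInfoDb::Seqinfo("chrT", 20000L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = sprintf("p%d", seq_along(summits)), summit = as.integer(summits))
  gr
}
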