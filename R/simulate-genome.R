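## Synthetic genome + annotation generator.
##
## The toy genome is laid out deterministically from the "annotation"
## substream of the master seed: spliced protein-coding gene models are
## placed left to right across the chromosomes with random intergenic gaps,
## followed by the retrotransposon loci; spike-in contigs are appended as
## extra sequences carried through the whole pipeline like chromosomes.
## Every gene with a long-enough 3'UTR gets one guaranteed RRACH instance
## ("GGACT" in transcript orientation) planted 10-200 bp downstream of its
## stop codon, every spike-in three instances, and every retro locus two, so
## the site planter never starves.

GAP_RANGE <- c(400L, 1200L)
MIN_EXON <- 80L

#' Generate a synthetic genome and its annotation
#'
#' Builds the random genome sequence and the full [GenomeAnnotation-class]
#' (gene models with 5'UTR/CDS/3'UTR and annotated stop codons on both
#' strands, spike-in contigs as single-exon transcripts, intergenic
#' retrotransposon loci). Deterministic for a fixed `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `annotation` (a `GenomeAnnotation`) and
#'   `genome` (a [Biostrings::DNAStringSet] including spike-in contigs).
#' @examples
#' gen <- generateAnnotation(simConfig(nGenes = 12, nChroms = 1,
#'                                     chromLength = 200000))
#' gen$annotation
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @export
generateAnnotation <- function(cfg) {
  validObject(cfg)
  withSubstream(cfg@seed, "annotation", {
    chromNames <- paste0("chr", seq_len(cfg@nChroms))

    ## -- draw gene structures ------------------------------------------------
    nG <- cfg@nGenes
    u5 <- sampleRange(nG, cfg@utr5Range)
    cds <- sampleRange(nG, cfg@cdsRange)
    cds <- pmax(6L, as.integer(3L * ceiling(cds / 3L)))
    u3 <- sampleRange(nG, cfg@utr3Range)
    txLen <- u5 + cds + u3
    strandG <- sample(c("+", "-"), nG, replace = TRUE)
    nExWant <- sampleRange(nG, cfg@exonsPerGene)

    exonW <- vector("list", nG)
    intronW <- vector("list", nG)
    for (i in seq_len(nG)) {
      nEx <- max(1L, min(nExWant[i], txLen[i] %/% (2L * MIN_EXON)))
      if (nEx == 1L) {
        exonW[[i]] <- txLen[i]
        intronW[[i]] <- integer()
      } else {
        w <- runif(nEx)
        ww <- as.integer(MIN_EXON + floor((txLen[i] - MIN_EXON * nEx) * w / sum(w)))
        ww[nEx] <- txLen[i] - sum(ww[-nEx])
        exonW[[i]] <- ww
        intronW[[i]] <- sampleRange(nEx - 1L, cfg@intronRange)
      }
    }
    geneSpan <- txLen + vapply(intronW, sum, 0L)

    ## -- draw retro locus structures ----------------------------------------
    rs <- cfg@retroSubfamilies
    retroSub <- rep(rs$name, rs$nLoci)
    retroCons <- rep(as.integer(rs$consensusLength), rs$nLoci)
    nR <- length(retroSub)
    retroLen <- as.integer(floor(retroCons * runif(nR, 0.92, 1)))
    retroStrand <- sample(c("+", "-"), nR, replace = TRUE)
    retroId <- paste0(retroSub, "_", unlist(lapply(rs$nLoci, seq_len)))

    ## -- place everything left to right across chromosomes -------------------
    spans <- c(geneSpan, retroLen)
    gaps <- sampleRange(length(spans), GAP_RANGE)
    chromOf <- integer(length(spans))
    start0 <- integer(length(spans))
    ci <- 1L; cursor <- 0L
    for (k in seq_along(spans)) {
      pos <- cursor + gaps[k]
      while (pos + spans[k] > cfg@chromLength - 200L) {
        ci <- ci + 1L
        if (ci > cfg@nChroms)
          stop(sprintf(
            "genome capacity exceeded: %d of %d elements unplaced; ",
            length(spans) - k + 1L, length(spans)),
            "increase chromLength/nChroms or reduce nGenes/retro loci",
            call. = FALSE)
        cursor <- 0L
        pos <- gaps[k]
      }
      chromOf[k] <- ci
      start0[k] <- pos
      cursor <- pos + spans[k]
    }
    geneChrom <- chromNames[chromOf[seq_len(nG)]]
    geneStart0 <- start0[seq_len(nG)]
    retroChrom <- chromNames[chromOf[nG + seq_len(nR)]]
    retroStart0 <- start0[nG + seq_len(nR)]

    ## -- random sequence -----------------------------------------------------
    alphabet <- c("A", "C", "G", "T")
    seqs <- lapply(seq_len(cfg@nChroms), function(i)
      sample(alphabet, cfg@chromLength, replace = TRUE, prob = cfg@baseFreqs))
    names(seqs) <- chromNames
    spikeNames <- names(cfg@spikeinLengths)
    for (sn in spikeNames)
      seqs[[sn]] <- sample(alphabet, cfg@spikeinLengths[[sn]],
                           replace = TRUE, prob = cfg@baseFreqs)

    ## -- per-gene transcript-order exon tables -------------------------------
    geneTab <- vector("list", nG)
    for (i in seq_len(nG)) {
      ex <- exonW[[i]]; intr <- intronW[[i]]; n <- length(ex)
      ascW <- if (strandG[i] == "+") ex else rev(ex)
      ascI <- if (strandG[i] == "+") intr else rev(intr)
      offAsc <- cumsum(c(0L, ascW[-n] + if (n > 1L) ascI else integer()))
      gStartAsc <- geneStart0[i] + offAsc
      gStartTx <- if (strandG[i] == "+") gStartAsc else rev(gStartAsc)
      geneTab[[i]] <- list(txStart0 = cumsum(c(0L, ex[-n])),
                           width = ex, gStart0 = gStartTx)
    }

    plantTx <- function(chrom, tab, strand, txPos, motif = "GGACT") {
      m <- mapTxInterval(txPos, txPos + nchar(motif), tab, strand)
      if (nrow(m) != 1L) return(FALSE)
      bases <- strsplit(motif, "")[[1]]
      if (strand == "-")
        bases <- strsplit(as.character(
          reverseComplement(DNAString(motif))), "")[[1]]
      seqs[[chrom]][(m[1, 1] + 1L):m[1, 2]] <<- bases
      TRUE
    }

    ## guaranteed stop-proximal RRACH per gene
    for (i in seq_len(nG)) {
      if (u3[i] < 30L) next
      for (try in 1:20) {
        d <- sampleRange(1L, c(10L, min(200L, u3[i] - 10L)))
        txPos <- u5[i] + cds[i] + d
        if (txPos + 5L <= txLen[i] &&
            plantTx(geneChrom[i], geneTab[[i]], strandG[i], txPos)) break
      }
    }
    ## spike-ins: three guaranteed instances each
    for (sn in spikeNames) {
      L <- cfg@spikeinLengths[[sn]]
      tab <- list(txStart0 = 0L, width = L, gStart0 = 0L)
      for (f in c(0.3, 0.5, 0.7))
        plantTx(sn, tab, "+", as.integer(floor(L * f)))
    }
    ## retro loci: two guaranteed instances each
    for (i in seq_len(nR)) {
      tab <- list(txStart0 = 0L, width = retroLen[i], gStart0 = retroStart0[i])
      for (f in c(0.35, 0.65))
        plantTx(retroChrom[i], tab, retroStrand[i],
                as.integer(floor(retroLen[i] * f)))
    }

    genome <- DNAStringSet(vapply(seqs, paste, "", collapse = ""))

    ## -- assemble annotation -------------------------------------------------
    si <- Seqinfo(seqnames = c(chromNames, spikeNames),
                  seqlengths = c(rep(cfg@chromLength, cfg@nChroms),
                                 unname(cfg@spikeinLengths)))
    geneIds <- sprintf("gene_%03d", seq_len(nG))
    txIds <- sprintf("tx_%03d", seq_len(nG))

    mkGR <- function(chrom, m, strand) {
      if (nrow(m) == 0L) return(GRanges(seqinfo = si))
      GRanges(chrom, IRanges(m[, 1] + 1L, m[, 2]), strand = strand,
              seqinfo = si)
    }
    exGRL <- cdsGRL <- u5GRL <- u3GRL <- vector("list", nG + nR +
                                                 length(spikeNames))
    stopList <- vector("list", nG)
    for (i in seq_len(nG)) {
      tab <- geneTab[[i]]
      exGRL[[i]] <- mkGR(geneChrom[i],
                         mapTxInterval(0L, txLen[i], tab, strandG[i]),
                         strandG[i])
      u5GRL[[i]] <- mkGR(geneChrom[i],
                         mapTxInterval(0L, u5[i], tab, strandG[i]), strandG[i])
      cdsGRL[[i]] <- mkGR(geneChrom[i],
                          mapTxInterval(u5[i], u5[i] + cds[i], tab, strandG[i]),
                          strandG[i])
      u3GRL[[i]] <- mkGR(geneChrom[i],
                         mapTxInterval(u5[i] + cds[i], txLen[i], tab,
                                       strandG[i]), strandG[i])
      sc <- mapTxInterval(u5[i] + cds[i] - 3L, u5[i] + cds[i], tab, strandG[i])
      stopList[[i]] <- GRanges(geneChrom[i],
                               IRanges(min(sc[, 1]) + 1L, max(sc[, 2])),
                               strand = strandG[i], seqinfo = si)
    }
    off <- nG
    for (j in seq_along(spikeNames)) {
      L <- cfg@spikeinLengths[[j]]
      exGRL[[off + j]] <- GRanges(spikeNames[j], IRanges(1L, L), strand = "+",
                                  seqinfo = si)
      cdsGRL[[off + j]] <- u5GRL[[off + j]] <- u3GRL[[off + j]] <-
        GRanges(seqinfo = si)
    }
    off <- nG + length(spikeNames)
    for (i in seq_len(nR)) {
      exGRL[[off + i]] <- GRanges(retroChrom[i],
                                  IRanges(retroStart0[i] + 1L,
                                          retroStart0[i] + retroLen[i]),
                                  strand = retroStrand[i], seqinfo = si)
      cdsGRL[[off + i]] <- u5GRL[[off + i]] <- u3GRL[[off + i]] <-
        GRanges(seqinfo = si)
    }

    allTxIds <- c(txIds, spikeNames, retroId)
    allGeneIds <- c(geneIds, spikeNames, retroId)
    txType <- c(rep("gene", nG), rep("spikein", length(spikeNames)),
                rep("retro", nR))
    spans <- unlist(GRangesList(lapply(exGRL, range)))
    tx <- spans
    mcols(tx) <- DataFrame(txId = allTxIds, geneId = allGeneIds,
                           txType = txType,
                           txLen = c(txLen, unname(cfg@spikeinLengths),
                                     retroLen),
                           u5Len = c(u5, rep(NA_integer_,
                                             length(spikeNames) + nR)),
                           cdsLen = c(cds, rep(NA_integer_,
                                               length(spikeNames) + nR)),
                           u3Len = c(u3, rep(NA_integer_,
                                             length(spikeNames) + nR)))
    names(exGRL) <- names(cdsGRL) <- names(u5GRL) <- names(u3GRL) <- allTxIds
    stopGR <- unlist(GRangesList(stopList))
    names(stopGR) <- txIds

    retro <- GRanges(retroChrom,
                     IRanges(retroStart0 + 1L, retroStart0 + retroLen),
                     strand = retroStrand, seqinfo = si)
    mcols(retro) <- DataFrame(locusId = retroId, subfamily = retroSub,
                              consensusLength = retroCons)

    ann <- new("GenomeAnnotation", seqinfo = si, transcripts = tx,
               exonsByTx = GRangesList(exGRL), cdsByTx = GRangesList(cdsGRL),
               utr5ByTx = GRangesList(u5GRL), utr3ByTx = GRangesList(u3GRL),
               stopCodons = stopGR, retroLoci = retro)
    list(annotation = ann, genome = genome)
  })
}

## Map a 0-based half-open transcript interval [s, e) to genomic blocks
## through a transcript-order exon table (txStart0/width/gStart0).
## Returns a matrix of ascending 0-based half-open (gs, ge) rows.
mapTxInterval <- function(s, e, tab, strand) {
  txEnd <- tab$txStart0 + tab$width
  hit <- which(tab$txStart0 < e & txEnd > s)
  gs <- ge <- numeric(length(hit))
  for (j in seq_along(hit)) {
    i <- hit[j]
    ts <- max(s, tab$txStart0[i]); te <- min(e, txEnd[i])
    if (strand == "+") {
      gs[j] <- tab$gStart0[i] + (ts - tab$txStart0[i])
      ge[j] <- gs[j] + (te - ts)
    } else {
      ge[j] <- tab$gStart0[i] + tab$width[i] - (ts - tab$txStart0[i])
      gs[j] <- ge[j] - (te - ts)
    }
  }
  o <- order(gs)
  cbind(gs = gs[o], ge = ge[o])
}

## Transcript-order exon table for one transcript, recovered from the
## genomic exon ranges (ascending = transcript order on "+", reversed on "-").
txExonTable <- function(annotation, txId) {
  ex <- annotation@exonsByTx[[txId]]
  strand <- as.character(strand(ex))[1]
  o <- order(start(ex))
  gs <- start(ex)[o] - 1L; w <- width(ex)[o]
  if (strand == "-") { gs <- rev(gs); w <- rev(w) }
  list(txStart0 = cumsum(c(0L, w[-length(w)])), width = w, gStart0 = gs,
       strand = strand)
}

## Extract the spliced transcript sequence (5'->3') for one transcript.
#' @importFrom Biostrings extractAt
extractTxSeq <- function(annotation, genome, txId) {
  ex <- annotation@exonsByTx[[txId]]
  strand <- as.character(strand(ex))[1]
  chrom <- as.character(seqnames(ex))[1]
  o <- order(start(ex))
  parts <- extractAt(genome[[chrom]], IRanges(start(ex)[o], end(ex)[o]))
  s <- do.call(Biostrings::xscat, as.list(parts))
  if (strand == "-") s <- reverseComplement(s)
  s
}
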