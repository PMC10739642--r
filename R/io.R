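## Readers/writers for the interchange formats: FASTA, GTF, BED12,
## bedGraph, ENCODE narrowPeak, and the plain TSV/CSV side tables.

#' Write / read aligned fragments as BED12
#'
#' Fragments are exchanged as BED12 (0-based half-open, blocks for spliced
#' fragments), via `rtracklayer`.
#'
#' @param frags a [FragmentSet-class].
#' @param path file path.
#' @return `writeFragmentsBED` returns `path` invisibly;
#'   `readFragmentsBED` returns a [FragmentSet-class].
#' @importFrom rtracklayer export import
#' @export
writeFragmentsBED <- function(frags, path) {
  gr <- fragments(frags)
  mcols(gr)$name <- sprintf("frag_%d", seq_along(gr))
  mcols(gr)$score <- 0L
  export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname writeFragmentsBED
#' @param sampleId,role,condition,replicate metadata for the imported set.
#' @param seqinfo optional `Seqinfo` to attach.
#' @export
readFragmentsBED <- function(path, sampleId = basename(path),
                             role = "input", condition = 1L,
                             replicate = 1L, seqinfo = NULL) {
  gr <- import(path, format = "bed")
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  keep <- intersect(c("blocks"), colnames(mcols(gr)))
  mcols(gr) <- mcols(gr)[, keep, drop = FALSE]
  fragmentSet(gr, sampleId = sampleId, role = role,
              condition = condition, replicate = replicate)
}

#' Write peaks as ENCODE narrowPeak
#'
#' BED6+4: `signalValue` is the fold enrichment, `pValue`/`qValue` are
#' -log10, `peak` is the summit offset from the peak start.
#'
#' @param peaks peak `GRanges` from [callPeaks()].
#' @param path file path.
#' @export
writeNarrowPeak <- function(peaks, path) {
  mlog10 <- function(x) -log10(pmax(x, 1e-300))
  df <- data.frame(
    chrom = as.character(seqnames(peaks)),
    start = start(peaks) - 1L,
    end = end(peaks),
    name = mcols(peaks)$name,
    score = pmin(1000L, as.integer(round(10 * mlog10(mcols(peaks)$q)))),
    strand = ".",
    signalValue = round(mcols(peaks)$foldEnrichment, 5),
    pValue = round(mlog10(mcols(peaks)$p), 5),
    qValue = round(mlog10(mcols(peaks)$q), 5),
    peak = mcols(peaks)$summit - start(peaks))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeNarrowPeak
#' @param seqinfo optional `Seqinfo`.
#' @export
readNarrowPeak <- function(path, seqinfo = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "signalValue",
                                        "pValue", "qValue", "peak"))
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  mcols(gr) <- DataFrame(name = df$name,
                         summit = df$start + df$peak + 1L,
                         pileup = NA_real_,
                         p = 10^(-df$pValue), q = 10^(-df$qValue),
                         foldEnrichment = df$signalValue)
  gr
}

#' Write a binned track as bedGraph
#'
#' One line per constant-value run (0-based half-open); zero-value runs are
#' kept so the track tiles the genome.
#'
#' @param track a [BinnedTrack-class].
#' @param path file path.
#' @export
writeBedGraph <- function(track, path) {
  bw <- track@binWidth
  sl <- seqlengths(track@seqinfo)
  rows <- list()
  for (ch in names(track@values)) {
    r <- rle(track@values[[ch]])
    e <- cumsum(r$lengths)
    s <- c(0, e[-length(e)])
    rows[[ch]] <- data.frame(chrom = ch, start = s * bw,
                             end = pmin(e * bw, sl[[ch]]),
                             value = r$values)
  }
  df <- do.call(rbind, rows)
  utils::write.table(format(df, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write the annotation as GTF
#'
#' Emits transcript, exon, CDS, five_prime_utr, three_prime_utr and
#' stop_codon features (1-based inclusive) with `gene_id`/`transcript_id`
#' attributes, via `rtracklayer`.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path file path.
#' @export
writeAnnotationGTF <- function(annotation, path) {
  tx <- annotation@transcripts
  feat <- function(grl, type) {
    gr <- unlist(grl)
    if (!length(gr)) return(GRanges(seqinfo = annotation@seqinfo))
    ids <- rep(names(grl), lengths(grl))
    mcols(gr) <- DataFrame(
      type = type,
      gene_id = mcols(tx)$geneId[match(ids, mcols(tx)$txId)],
      transcript_id = ids)
    if (type == "CDS") {
      ## reading-frame phase per CDS block, in transcript order
      ph <- integer(length(gr))
      for (id in unique(ids)) {
        i <- which(ids == id)
        o <- if (as.character(strand(gr))[i[1]] == "-") rev(order(start(gr)[i]))
             else order(start(gr)[i])
        prev <- cumsum(c(0L, width(gr)[i][o][-length(i)]))
        ph[i[o]] <- (3L - prev %% 3L) %% 3L
      }
      mcols(gr)$phase <- ph
    }
    names(gr) <- NULL
    gr
  }
  txGr <- GenomicRanges::granges(tx)
  mcols(txGr) <- DataFrame(type = "transcript",
                           gene_id = mcols(tx)$geneId,
                           transcript_id = mcols(tx)$txId)
  sc <- annotation@stopCodons
  scGr <- GenomicRanges::granges(sc)
  mcols(scGr) <- DataFrame(
    type = "stop_codon",
    gene_id = mcols(tx)$geneId[match(names(sc), mcols(tx)$txId)],
    transcript_id = names(sc))
  names(scGr) <- NULL
  all <- c(txGr, feat(annotation@exonsByTx, "exon"),
           feat(annotation@cdsByTx, "CDS"),
           feat(annotation@utr5ByTx, "five_prime_utr"),
           feat(annotation@utr3ByTx, "three_prime_utr"), scGr)
  all <- sort(all, ignore.strand = TRUE)
  export(all, path, format = "gtf")
  invisible(path)
}

#' Write / read RepeatMasker-style retro locus tables
#'
#' TSV with columns chrom, start, end (0-based half-open), strand,
#' subfamily, consensusLength.
#'
#' @param loci retro `GRanges` (e.g. `retroLoci(annotation)`).
#' @param path file path.
#' @export
writeRetroTSV <- function(loci, path) {
  df <- data.frame(chrom = as.character(seqnames(loci)),
                   start = start(loci) - 1L, end = end(loci),
                   strand = as.character(strand(loci)),
                   subfamily = mcols(loci)$subfamily,
                   consensusLength = mcols(loci)$consensusLength)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRetroTSV
#' @param seqinfo optional `Seqinfo`.
#' @export
readRetroTSV <- function(path, seqinfo = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                strand = df$strand)
  if (!is.null(seqinfo)) {
    GenomeInfoDb::seqlevels(gr) <- seqlevels(seqinfo)
    GenomeInfoDb::seqinfo(gr) <- seqinfo
  }
  mcols(gr) <- DataFrame(
    locusId = sprintf("%s_%d", df$subfamily,
                      stats::ave(seq_len(nrow(df)), df$subfamily,
                                 FUN = seq_along)),
    subfamily = df$subfamily, consensusLength = df$consensusLength)
  gr
}

#' Write a full simulated experiment to disk
#'
#' Genome FASTA, annotation GTF, one BED12 per library, truth TSV, retro
#' locus TSV and a sample sheet, all plain text.
#'
#' @param se a [SimulatedExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @importFrom Biostrings writeXStringSet
#' @export
writeSimulation <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(se@genome, file.path(dir, "genome.fa"))
  writeAnnotationGTF(se@annotation, file.path(dir, "annotation.gtf"))
  writeRetroTSV(retroLoci(se@annotation), file.path(dir, "retro_loci.tsv"))
  s <- truthSites(se@truth)
  utils::write.table(
    data.frame(chrom = as.character(seqnames(s)), pos0 = start(s) - 1L,
               strand = as.character(strand(s)), txId = mcols(s)$txId,
               stoichiometry = mcols(s)$stoichiometry,
               condition = mcols(s)$condition, kind = mcols(s)$kind),
    file.path(dir, "truth_sites.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  sheet <- do.call(rbind, lapply(se@samples, function(fs)
    data.frame(sampleId = fs@sampleId, role = fs@role,
               condition = fs@condition, replicate = fs@replicate,
               bed = paste0(fs@sampleId, ".bed"))))
  utils::write.table(sheet, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (fs in se@samples)
    writeFragmentsBED(fs, file.path(dir, paste0(fs@sampleId, ".bed")))
  invisible(dir)
}

#' Write / read qPCR Ct tables
#'
#' CSV with sample, target, assay, Ct (empty = censored) and inputFraction.
#'
#' @param qpcr a [simulateQpcr()]-style data.frame.
#' @param path file path.
#' @export
writeQpcrCSV <- function(qpcr, path) {
  utils::write.csv(qpcr, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeQpcrCSV
#' @export
readQpcrCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!"censored" %in% names(df)) df$censored <- is.na(df$Ct)
  df
}
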