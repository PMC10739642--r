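## Model-based m6A peak calling: IP pileup per 10-bp bin against a
## MACS-style Poisson local background estimated from the input library,
## with Benjamini-Hochberg q-values over all non-empty bins.

#' Peak caller configuration
#'
#' @slot effectiveSize effective genome/transcriptome size G in bp (`NA`
#'   means the sum of the chromosome lengths of the data at hand). MACS-style
#'   published values are 242010196 for mouse and 117608789 for zebrafish
#'   transcriptomes.
#' @slot qCutoff BH FDR cutoff (peaks require q < qCutoff; default 0.05).
#' @slot binWidth candidate bin width in bp (default 10).
#' @slot localWindows the local-background window sizes in bp.
#' @slot mergeGap significant bins closer than this are merged (bp).
#' @slot minPeakLength merged intervals shorter than this are dropped (bp),
#'   default 150, about one sonicated fragment.
#' @export
setClass("PeakCallerConfig", representation(
  effectiveSize = "numeric",
  qCutoff = "numeric",
  binWidth = "integer",
  localWindows = "numeric",
  mergeGap = "integer",
  minPeakLength = "integer"
))

setValidity("PeakCallerConfig", function(object) {
  if (!is.na(object@effectiveSize) && object@effectiveSize <= 0)
    return("effectiveSize must be > 0")
  if (object@qCutoff <= 0 || object@qCutoff > 1)
    return("qCutoff must be in (0, 1]")
  if (object@binWidth <= 0L) return("binWidth must be > 0")
  TRUE
})

#' @describeIn PeakCallerConfig-class constructor.
#' @param effectiveSize,qCutoff,binWidth,localWindows,mergeGap,minPeakLength
#'   see the class slots.
#' @export
peakCallerConfig <- function(effectiveSize = NA_real_, qCutoff = 0.05,
                             binWidth = 10L,
                             localWindows = c(1000, 5000, 10000),
                             mergeGap = 100L, minPeakLength = 150L) {
  new("PeakCallerConfig", effectiveSize = as.numeric(effectiveSize),
      qCutoff = qCutoff, binWidth = as.integer(binWidth),
      localWindows = as.numeric(localWindows),
      mergeGap = as.integer(mergeGap),
      minPeakLength = as.integer(minPeakLength))
}

#' Effective transcriptome size
#'
#' Total bases in the union of exons of all annotated transcripts
#' (spike-in contigs and retro loci included). The natural `effectiveSize`
#' for RNA IP data: with the full genome as G the genome-wide background
#' rate is diluted by the untranscribed desert and depleted-but-expressed
#' regions are miscalled as enriched.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @return numeric size in bp.
#' @export
effectiveTranscriptomeSize <- function(annotation) {
  sum(as.numeric(width(reduce(unstrand(unlist(annotation@exonsByTx))))))
}

#' Collapse PCR duplicates
#'
#' Fragments with identical (chromosome, start, end, strand) are collapsed
#' to one; the result is canonically sorted and independent of input order.
#' Fragments differing only by strand are both retained.
#'
#' @param frags a [FragmentSet-class].
#' @return the deduplicated, sorted [FragmentSet-class].
#' @export
deduplicate <- function(frags) {
  gr <- fragments(frags)
  if (length(gr)) {
    key <- paste(as.character(seqnames(gr)), start(gr), end(gr),
                 as.character(strand(gr)), sep = ":")
    gr <- gr[!duplicated(key)]
    gr <- gr[order(as.factor(seqnames(gr)), start(gr), end(gr),
                   as.factor(strand(gr)))]
  }
  out <- frags
  out@fragments <- gr
  out
}

#' Poisson upper-tail probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`, the enrichment test of the
#' model-based caller. Evaluated through the regularised-gamma machinery of
#' `ppois`, which is numerically stable far into the tail.
#'
#' @param k observed count(s), non-negative integers.
#' @param lambda expected count(s), > 0.
#' @return upper-tail probabilities.
#' @examples
#' poissonUpperTail(1, 1)  # 1 - exp(-1)
#' @export
poissonUpperTail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be non-negative integers", call. = FALSE)
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up BH adjustment with monotonicity enforcement; ties are stable.
#'
#' @param p p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bhQvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Local Poisson background
#'
#' MACS-style local expected pileup for candidate bins: for each window size
#' `w`, `lambda_w = (input fragments overlapping the w-window centred on the
#' bin) * meanFragBins * binWidth / w * depthRatio`, where `meanFragBins` is
#' the mean number of bins an input fragment overlaps (so lambda is on the
#' scale of the per-bin fragment-overlap pileup); the genome-wide rate is
#' `lambda_BG = totalInput * meanFragBins / (G / binWidth) * depthRatio`.
#' Besides the kilobase-scale windows, the control contributes a
#' fragment-size window (`dWindow`, about one fragment length) -- without
#' it, coverage concentrated on exons at sub-kilobase scale inflates the
#' test and an IP identical to its input yields spurious calls. The local
#' rate is `lambda_local = max(lambda_BG, lambda_d, lambda_1k, lambda_5k,
#' lambda_10k)`.
#'
#' @param inpStarts0,inpEnds0 sorted 0-based starts / half-open ends of the
#'   input fragment spans on one chromosome.
#' @param bins 0-based bin indices to evaluate.
#' @param cfg a [PeakCallerConfig-class].
#' @param depthRatio total IP fragments / total input fragments.
#' @param lambdaBG the genome-wide rate (already depth-scaled).
#' @param meanFragBins mean bins overlapped per input fragment.
#' @param dWindow fragment-size window in bp (default
#'   `meanFragBins * binWidth`).
#' @return matrix with one row per bin: the per-window rates and
#'   `lambdaLocal`.
#' @export
localLambda <- function(inpStarts0, inpEnds0, bins, cfg, depthRatio,
                        lambdaBG, meanFragBins,
                        dWindow = meanFragBins * cfg@binWidth) {
  bw <- cfg@binWidth
  center <- bins * bw + bw / 2
  windows <- c(dWindow, cfg@localWindows)
  out <- matrix(NA_real_, length(bins), length(windows) + 2L)
  colnames(out) <- c("lambdaBG", "lambdaD",
                     paste0("lambda", cfg@localWindows), "lambdaLocal")
  out[, "lambdaBG"] <- lambdaBG
  for (j in seq_along(windows)) {
    w <- windows[j]
    winS <- center - w / 2
    winE <- center + w / 2
    cnt <- findInterval(winE - 1, inpStarts0) - findInterval(winS, inpEnds0)
    out[, j + 1L] <- cnt * meanFragBins * bw / w * depthRatio
  }
  out[, "lambdaLocal"] <- do.call(pmax, c(
    lapply(seq_len(ncol(out) - 1L), function(j) out[, j]), list(0)))
  out
}

#' Call m6A peaks from IP versus input fragments
#'
#' Per 10-bp bin, the IP fragment-overlap pileup is tested against the
#' Poisson local background ([localLambda()]); BH q-values are computed over
#' all bins with non-zero pileup, significant bins (q < cutoff) closer than
#' `mergeGap` are merged, and merged intervals shorter than `minPeakLength`
#' are dropped. Each peak reports the minimum-p bin's p/q, the summit
#' (centre of the maximum-pileup significant bin, leftmost on ties), its
#' pileup, and `foldEnrichment = pileup / lambdaLocal` at the summit.
#' Spike-in contigs are processed exactly like chromosomes. Inputs are
#' expected to be deduplicated (see [deduplicate()]); the caller never
#' collapses duplicates itself.
#'
#' @param ip,inp [FragmentSet-class]s (IP and matched input).
#' @param cfg a [PeakCallerConfig-class].
#' @return `GRanges` of disjoint peaks with metadata columns `name`,
#'   `summit` (1-based genomic position), `pileup`, `p`, `q`,
#'   `foldEnrichment`.
#' @export
callPeaks <- function(ip, inp, cfg = peakCallerConfig()) {
  validObject(cfg)
  bw <- cfg@binWidth
  si <- seqinfo(ip)
  emptyRes <- function() {
    gr <- GRanges(seqinfo = si)
    mcols(gr) <- DataFrame(name = character(), summit = integer(),
                           pileup = numeric(), p = numeric(), q = numeric(),
                           foldEnrichment = numeric())
    gr
  }
  if (length(ip) == 0L) {
    warning("empty IP fragment set; no peaks called")
    return(emptyRes())
  }
  ipCnt <- binCoverage(ip, bw, normalize = "count")
  totIP <- length(ip)
  totInp <- length(inp)
  G <- if (is.na(cfg@effectiveSize)) sum(as.numeric(seqlengths(si)))
       else cfg@effectiveSize

  inpGr <- fragments(inp)
  if (totInp > 0) {
    inpCnt <- binCoverage(inp, bw, normalize = "count")
    depthRatio <- totIP / totInp
    meanFragBins <- sum(unlist(inpCnt@values, use.names = FALSE)) / totInp
    lambdaBG <- totInp * meanFragBins / (G / bw) * depthRatio
  } else {
    ## no input control: genome-wide uniform prior from the IP library
    warning("input has zero fragments; background taken from IP totals")
    depthRatio <- 1
    meanFragBins <- sum(unlist(ipCnt@values, use.names = FALSE)) / totIP
    lambdaBG <- totIP * meanFragBins / (G / bw)
  }

  chromBins <- list(); chromK <- list(); chromLam <- list()
  for (ch in names(ipCnt@values)) {
    v <- ipCnt@values[[ch]]
    nz <- which(v > 0) - 1L
    if (!length(nz)) next
    onCh <- inpGr[as.character(seqnames(inpGr)) == ch]
    s0 <- sort(start(onCh) - 1L)
    e0 <- sort(end(onCh))
    lam <- localLambda(s0, e0, nz, cfg, depthRatio, lambdaBG, meanFragBins)
    chromBins[[ch]] <- nz
    chromK[[ch]] <- v[nz + 1L]
    chromLam[[ch]] <- lam[, "lambdaLocal"]
  }
  if (!length(chromBins)) return(emptyRes())

  k <- unlist(chromK, use.names = FALSE)
  lam <- pmax(unlist(chromLam, use.names = FALSE), 1e-12)
  p <- poissonUpperTail(k, lam)
  q <- bhQvalues(p)

  nPer <- vapply(chromBins, length, 0L)
  chrom <- rep(names(chromBins), nPer)
  bins <- unlist(chromBins, use.names = FALSE)
  sig <- q < cfg@qCutoff
  if (!any(sig)) return(emptyRes())

  sl <- seqlengths(si)
  binGR <- GRanges(chrom[sig],
                   IRanges(bins[sig] * bw + 1L,
                           pmin((bins[sig] + 1L) * bw,
                                sl[chrom[sig]])),
                   seqinfo = si)
  mcols(binGR) <- DataFrame(k = k[sig], lam = lam[sig], p = p[sig],
                            q = q[sig])
  peaks <- reduce(binGR, min.gapwidth = cfg@mergeGap + 1L)
  peaks <- peaks[width(peaks) >= cfg@minPeakLength]
  if (!length(peaks)) return(emptyRes())

  h <- findOverlaps(binGR, peaks)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  summit <- pval <- qval <- pile <- fold <- numeric(length(peaks))
  for (i in seq_along(peaks)) {
    mem <- qh[sh == i]
    pv <- mcols(binGR)$p[mem]
    pval[i] <- min(pv)
    qval[i] <- min(mcols(binGR)$q[mem])
    kk <- mcols(binGR)$k[mem]
    best <- mem[which.max(kk)]            # leftmost max (bins are sorted)
    pile[i] <- mcols(binGR)$k[best]
    fold[i] <- pile[i] / mcols(binGR)$lam[best]
    summit[i] <- start(binGR)[best] - 1L + bw %/% 2L + 1L
  }
  mcols(peaks) <- DataFrame(name = sprintf("peak_%d", seq_along(peaks)),
                            summit = as.integer(summit), pileup = pile,
                            p = pval, q = qval, foldEnrichment = fold)
  sort(peaks)
}
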