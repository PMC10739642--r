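## Fragment library simulation: fragmentation in transcript space, IP
## selection as per-fragment Bernoulli retention renormalised to a fixed
## library depth, then projection of transcript intervals to genomic blocks
## through the exon structure (spliced fragments are emitted as BED12-style
## split blocks).

## Concatenated transcript-order exon catalog over all transcripts, plus a
## "global transcript coordinate" (transcripts laid end to end with 1-bp
## guards) so projection is a pair of findInterval() calls.
buildTxCatalog <- function(annotation) {
  tx <- annotation@transcripts
  ids <- mcols(tx)$txId
  tabs <- lapply(ids, function(id) txExonTable(annotation, id))
  nEx <- vapply(tabs, function(t) length(t$width), 0L)
  txLen <- vapply(tabs, function(t) sum(t$width), 0)
  txOffset <- cumsum(c(0, txLen[-length(txLen)] + 1))
  list(
    ids = ids,
    chrom = as.character(seqnames(tx)),
    strandPlus = as.character(strand(tx)) == "+",
    txLen = txLen,
    txOffset = txOffset,
    rowTx = rep(seq_along(ids), nEx),
    rowTxStart0 = unlist(lapply(tabs, `[[`, "txStart0"), use.names = FALSE),
    rowWidth = unlist(lapply(tabs, `[[`, "width"), use.names = FALSE),
    rowGStart0 = unlist(lapply(tabs, `[[`, "gStart0"), use.names = FALSE),
    rowGlobal = rep(txOffset, nEx) +
      unlist(lapply(tabs, `[[`, "txStart0"), use.names = FALSE)
  )
}

## Project fragments given as (txIdx, start0, len) in transcript coordinates
## to a GRanges of genomic spans with a relative-blocks column.
projectFragments <- function(cat, txIdx, start0, len, seqinfo) {
  n <- length(txIdx)
  if (n == 0L) {
    gr <- GRanges(seqinfo = seqinfo)
    mcols(gr)$blocks <- IRangesList()
    return(gr)
  }
  gS <- cat$txOffset[txIdx] + start0
  gE <- gS + len - 1
  first <- findInterval(gS, cat$rowGlobal)
  last <- findInterval(gE, cat$rowGlobal)
  plus <- cat$strandPlus[txIdx]

  rowEnd0 <- cat$rowTxStart0 + cat$rowWidth
  blockG <- function(row, ts, te) {
    ## genomic (gs0, ge0) of tx interval [ts, te) inside exon row
    p <- cat$strandPlus[cat$rowTx[row]]
    gs <- ifelse(p, cat$rowGStart0[row] + (ts - cat$rowTxStart0[row]),
                 cat$rowGStart0[row] + cat$rowWidth[row] -
                   (te - cat$rowTxStart0[row]))
    list(gs = gs, ge = gs + (te - ts))
  }

  ## span endpoints come from the first/last transcript-order exon only
  tsF <- pmax(start0, cat$rowTxStart0[first])
  teF <- pmin(start0 + len, rowEnd0[first])
  tsL <- pmax(start0, cat$rowTxStart0[last])
  teL <- pmin(start0 + len, rowEnd0[last])
  bF <- blockG(first, tsF, teF)
  bL <- blockG(last, tsL, teL)
  spanS <- ifelse(plus, bF$gs, bL$gs)
  spanE <- ifelse(plus, bL$ge, bF$ge)

  ## full block expansion
  nb <- last - first + 1L
  frag <- rep.int(seq_len(n), nb)
  row <- first[frag] + (sequence(nb) - 1L)
  ts <- pmax(start0[frag], cat$rowTxStart0[row])
  te <- pmin(start0[frag] + len[frag], rowEnd0[row])
  b <- blockG(row, ts, te)
  relStart <- b$gs - spanS[frag] + 1
  bw <- b$ge - b$gs
  ## ascending genomic order within each fragment ("-" strand reversed)
  off <- cumsum(c(0L, nb[-n]))
  pos <- sequence(nb)
  ord <- off[frag] + ifelse(plus[frag], pos, nb[frag] - pos + 1L)
  rs <- ws <- numeric(length(ord))
  rs[ord] <- relStart; ws[ord] <- bw
  blocks <- IRanges::relist(IRanges(as.integer(rs), width = as.integer(ws)),
                            IRanges::PartitioningByEnd(cumsum(nb)))

  gr <- GRanges(cat$chrom[txIdx], IRanges(spanS + 1, spanE),
                strand = ifelse(plus, "+", "-"), seqinfo = seqinfo)
  mcols(gr)$blocks <- blocks
  gr
}

#' Simulate an aligned-fragment library
#'
#' Fragments are drawn per transcript proportionally to
#' `expression x transcript length`, with start uniform along the transcript
#' and length normal(`fragmentLengthMean`, `fragmentLengthSd`) truncated at
#' 30 bp. For `role = "IP"` each candidate fragment is retained by a
#' Bernoulli draw with probability proportional to
#' `stoichiometry x ipEnrichmentFactor` when it covers a planted site (the
#' most methylated covered site counts) and to `backgroundBindingRate`
#' otherwise; accepted fragments are renormalised to exactly
#' `nFragmentsPerSample`, mirroring equimolar library pooling. Transcript
#' coordinates are projected to the genome through the exon blocks, so
#' fragments spanning introns carry split blocks.
#'
#' @param annotation,genome unused `genome` kept for symmetry; annotation from
#'   [generateAnnotation()].
#' @param truth a [SyntheticTruth-class] (ignored for `role = "input"`).
#' @param expression data.frame from [simulateExpression()].
#' @param cfg the [SimConfig-class].
#' @param role `"IP"` or `"input"`.
#' @param condition,replicate which library to draw (selects the site set
#'   and the RNG substream).
#' @return a [FragmentSet-class].
#' @export
simulateFragments <- function(annotation, truth, expression, cfg,
                              role = c("input", "IP"),
                              condition = 1L, replicate = 1L,
                              genome = NULL) {
  role <- match.arg(role)
  cat <- buildTxCatalog(annotation)
  w <- expression$relAbundance[match(cat$ids, expression$txId)]
  if (is.null(w) || all(is.na(w)) || !length(w))
    stop("empty expression table", call. = FALSE)
  w[is.na(w)] <- 0
  w <- w * cat$txLen
  N <- cfg@nFragmentsPerSample
  stream <- sprintf("fragments/c%d/r%d/%s", condition, replicate, role)

  drawCandidates <- function(k) {
    txIdx <- sample.int(length(w), k, replace = TRUE, prob = w)
    len <- pmax(30, round(stats::rnorm(k, cfg@fragmentLengthMean,
                                       cfg@fragmentLengthSd)))
    len <- pmin(len, cat$txLen[txIdx])
    start0 <- floor(stats::runif(k) * (cat$txLen[txIdx] - len + 1))
    list(txIdx = txIdx, start0 = start0, len = len)
  }

  res <- withSubstream(cfg@seed, stream, {
    if (N == 0L) {
      list(txIdx = integer(), start0 = numeric(), len = numeric())
    } else if (role == "input") {
      drawCandidates(N)
    } else {
      s <- truth@sites
      keep <- (mcols(s)$kind != "gene") |
        (!is.na(mcols(s)$condition) & mcols(s)$condition == condition)
      s <- s[keep]
      siteGlobal <- cat$txOffset[match(mcols(s)$txId, cat$ids)] +
        mcols(s)$txPos
      siteIR <- IRanges(as.integer(siteGlobal) + 1L, width = 1L)
      stoich <- mcols(s)$stoichiometry
      E <- cfg@ipEnrichmentFactor
      bgr <- cfg@backgroundBindingRate

      acc <- list(txIdx = integer(), start0 = numeric(), len = numeric())
      rate <- 0.1; tries <- 0L
      while (length(acc$txIdx) < N) {
        tries <- tries + 1L
        if (tries > 200L)
          stop("IP selection accepts too few fragments; ",
               "check backgroundBindingRate and planted sites", call. = FALSE)
        k <- min(2e6, max(5e4, ceiling((N - length(acc$txIdx)) / rate * 1.2)))
        cand <- drawCandidates(k)
        gS <- cat$txOffset[cand$txIdx] + cand$start0
        fragIR <- IRanges(as.integer(gS) + 1L, width = as.integer(cand$len))
        wfrag <- rep(bgr, k)
        if (length(siteIR)) {
          h <- IRanges::findOverlaps(fragIR, siteIR)
          qh <- S4Vectors::queryHits(h)
          st <- stoich[S4Vectors::subjectHits(h)]
          o <- order(st)
          best <- numeric(k)
          best[qh[o]] <- st[o]
          wfrag[best > 0] <- best[best > 0] * E
        }
        ok <- stats::runif(k) < wfrag / E
        if (!any(ok)) {
          if (bgr == 0 && !length(siteIR))
            stop("IP selection accepts no fragments: no sites and zero ",
                 "background binding", call. = FALSE)
          next
        }
        rate <- max(sum(ok) / k, 1e-4)
        acc$txIdx <- c(acc$txIdx, cand$txIdx[ok])
        acc$start0 <- c(acc$start0, cand$start0[ok])
        acc$len <- c(acc$len, cand$len[ok])
      }
      lapply(acc, function(x) x[seq_len(N)])
    }
  })

  gr <- projectFragments(cat, res$txIdx, res$start0, res$len,
                         annotation@seqinfo)
  new("FragmentSet",
      sampleId = sprintf("c%d_r%d_%s", condition, replicate, role),
      role = role, condition = as.integer(condition),
      replicate = as.integer(replicate), fragments = gr)
}

#' Simulate a complete experiment
#'
#' One call producing genome, annotation, planted truth, expression and all
#' IP/input libraries for every condition x replicate of `cfg`, each from
#' its own RNG substream of `cfg@seed`.
#'
#' @param cfg a [SimConfig-class].
#' @return a [SimulatedExperiment-class]; libraries are named
#'   `c<condition>_r<replicate>_<role>`.
#' @examples
#' \donttest{
#' se <- simulateExperiment(simConfig(seed = 7, nGenes = 30, nChroms = 1,
#'                                    chromLength = 400000, nM6aSites = 20,
#'                                    nFragmentsPerSample = 20000))
#' se
#' }
#' @export
simulateExperiment <- function(cfg) {
  gen <- generateAnnotation(cfg)
  truth <- plantSites(gen$annotation, gen$genome, cfg)
  expr <- simulateExpression(gen$annotation, cfg)
  samples <- list()
  for (cond in seq_len(cfg@conditions))
    for (rep_ in seq_len(cfg@replicates))
      for (role in c("input", "IP")) {
        fs <- simulateFragments(gen$annotation, truth, expr, cfg,
                                role = role, condition = cond,
                                replicate = rep_)
        samples[[fs@sampleId]] <- fs
      }
  new("SimulatedExperiment", config = cfg, genome = gen$genome,
      annotation = gen$annotation, truth = truth, expression = expr,
      samples = samples)
}
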