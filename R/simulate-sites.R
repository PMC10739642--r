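## Planting m6A sites on RRACH adenosines.

#' Plant ground-truth m6A sites
#'
#' Selects `cfg@nM6aSites` methylation sites per condition from the actual
#' RRACH occurrences in exonic transcript sequence: each site is the A of an
#' RRACH pentamer on the transcript strand. A fraction `cfg@stopCodonBias`
#' of sites (Bernoulli per site) is drawn from the pool within 400 bp of an
#' annotated stop codon -- weighted towards the stop codon
#' (`exp(-distance/100)`), reproducing the sharply stop-centred m6A density
#' of the assay -- the rest uniformly from the distal pool; sites of one
#' condition are kept at least `cfg@minSiteSpacing` bp apart and conditions
#' never share a site (disjoint draws without replacement). Per-site
#' stoichiometry is uniform over `cfg@stoichiometryRange`. Modified spike-in
#' contigs are marked at every RRACH (stoichiometry 1); each locus of a
#' methylated retrotransposon subfamily receives up to two sites.
#'
#' @param annotation,genome output of [generateAnnotation()].
#' @param cfg the [SimConfig-class].
#' @return a [SyntheticTruth-class].
#' @importFrom Biostrings matchPattern
#' @export
plantSites <- function(annotation, genome, cfg) {
  withSubstream(cfg@seed, "sites", {
    tx <- annotation@transcripts
    si <- annotation@seqinfo

    siteRows <- function(txId, txPosVec) {
      ## genomic coordinates (1-based) of 0-based transcript positions
      tab <- txExonTable(annotation, txId)
      vapply(txPosVec, function(p)
        mapTxInterval(p, p + 1L, tab, tab$strand)[1, 1] + 1, 0)
    }
    rrachTxPos <- function(txId) {
      s <- extractTxSeq(annotation, genome, txId)
      m <- matchPattern("RRACH", s, fixed = FALSE)
      start(m) + 1L  # 0-based transcript coordinate of the A (position 3)
    }

    ## ---- gene-site pool ----------------------------------------------------
    geneTx <- mcols(tx)$txId[mcols(tx)$txType == "gene"]
    poolTx <- character(); poolPos <- integer(); poolG <- numeric()
    poolChrom <- character(); poolStrand <- character()
    for (id in geneTx) {
      p <- rrachTxPos(id)
      if (!length(p)) next
      g <- siteRows(id, p)
      poolTx <- c(poolTx, rep(id, length(p)))
      poolPos <- c(poolPos, p)
      poolG <- c(poolG, g)
      k <- match(id, mcols(tx)$txId)
      poolChrom <- c(poolChrom, rep(as.character(seqnames(tx))[k], length(p)))
      poolStrand <- c(poolStrand, rep(as.character(strand(tx))[k], length(p)))
    }
    nPool <- length(poolPos)
    prox <- logical(nPool)
    if (nPool) {
      sc <- annotation@stopCodons[poolTx]
      d <- pmax(0, pmax(start(sc) - poolG, poolG - end(sc)))
      prox <- d <= 400
    }

    n <- cfg@nM6aSites
    used <- logical(nPool)
    out <- list()
    for (cond in seq_len(cfg@conditions)) {
      if (n == 0L) next
      nProx <- stats::rbinom(1L, n, cfg@stopCodonBias)
      sel <- integer(); selChrom <- character(); selPos <- numeric()
      pick <- function(fromProx, k) {
        got <- 0L
        cand <- which(!used & (prox == fromProx))
        ## proximal candidates are drawn preferentially near the stop codon
        ## (exp(-d/100bp)), giving the sharply stop-centred site density the
        ## assay shows; distal candidates are drawn uniformly
        cand <- if (fromProx && length(cand))
          cand[sample.int(length(cand), prob = exp(-d[cand] / 100))]
        else cand[sample.int(length(cand))]
        for (i in cand) {
          if (got == k) break
          same <- selChrom == poolChrom[i]
          if (!any(abs(selPos[same] - poolG[i]) < cfg@minSiteSpacing)) {
            sel <<- c(sel, i)
            selChrom <<- c(selChrom, poolChrom[i])
            selPos <<- c(selPos, poolG[i])
            got <- got + 1L
          }
        }
        if (got < k)
          stop(sprintf(paste0(
            "too few eligible RRACH motifs: needed %d %s sites for ",
            "condition %d but only %d could be placed (pool of %d, ",
            "spacing %d bp)"), k,
            if (fromProx) "stop-codon-proximal" else "distal",
            cond, got, length(cand), cfg@minSiteSpacing),
            call. = FALSE)
      }
      pick(TRUE, nProx)
      pick(FALSE, n - nProx)
      used[sel] <- TRUE
      out[[length(out) + 1L]] <- DataFrame(
        chrom = poolChrom[sel], pos = poolG[sel], strand = poolStrand[sel],
        txId = poolTx[sel], txPos = poolPos[sel],
        stoichiometry = runif(length(sel), cfg@stoichiometryRange[1],
                              cfg@stoichiometryRange[2]),
        condition = cond, kind = "gene")
    }

    ## ---- spike-in sites ----------------------------------------------------
    for (sn in names(cfg@spikeinModified)[cfg@spikeinModified]) {
      p <- rrachTxPos(sn)
      if (length(p))
        out[[length(out) + 1L]] <- DataFrame(
          chrom = sn, pos = p + 1, strand = "+", txId = sn, txPos = p,
          stoichiometry = 1, condition = NA_integer_, kind = "spikein")
    }

    ## ---- retrotransposon sites ---------------------------------------------
    rl <- annotation@retroLoci
    methSub <- cfg@retroSubfamilies$name[cfg@retroSubfamilies$methylated]
    for (i in which(mcols(rl)$subfamily %in% methSub)) {
      id <- mcols(rl)$locusId[i]
      p <- rrachTxPos(id)
      if (!length(p)) next
      p <- sort(p[sample.int(length(p), min(2L, length(p)))])
      out[[length(out) + 1L]] <- DataFrame(
        chrom = as.character(seqnames(rl))[i], pos = siteRows(id, p),
        strand = as.character(strand(rl))[i], txId = id, txPos = p,
        stoichiometry = runif(length(p), cfg@stoichiometryRange[1],
                              cfg@stoichiometryRange[2]),
        condition = NA_integer_, kind = "retro")
    }

    df <- if (length(out)) do.call(rbind, out) else
      DataFrame(chrom = character(), pos = numeric(), strand = character(),
                txId = character(), txPos = integer(),
                stoichiometry = numeric(), condition = integer(),
                kind = character())
    sites <- GRanges(df$chrom, IRanges(df$pos, width = 1),
                     strand = df$strand, seqinfo = si)
    mcols(sites) <- DataFrame(txId = df$txId, txPos = as.integer(df$txPos),
                              stoichiometry = df$stoichiometry,
                              condition = df$condition, kind = df$kind)
    retroTruth <- stats::setNames(cfg@retroSubfamilies$methylated,
                                  cfg@retroSubfamilies$name)
    new("SyntheticTruth", sites = sites,
        spikeinStatus = cfg@spikeinModified, retroTruth = retroTruth)
  })
}

#' Verify planted sites sit on RRACH adenosines
#'
#' Sequence-lookup check of the truth invariant: for every planted site the
#' strand-oriented genomic 5-mer centred on the site (A at position 3)
#' matches `[AG][AG]AC[ACT]`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param genome the `DNAStringSet` genome.
#' @return logical vector, one element per site.
#' @importFrom Biostrings subseq
#' @export
siteMotifCheck <- function(truth, genome) {
  s <- truth@sites
  if (!length(s)) return(logical())
  vapply(seq_along(s), function(i) {
    chrom <- as.character(seqnames(s))[i]
    p <- start(s)[i]
    if (p - 2 < 1 || p + 2 > length(genome[[chrom]])) return(FALSE)
    w <- subseq(genome[[chrom]], p - 2, p + 2)
    if (as.character(strand(s))[i] == "-") w <- reverseComplement(w)
    grepl("^[AG][AG]AC[ACT]$", as.character(w))
  }, logical(1))
}

#' Simulate per-transcript expression
#'
#' Relative transcript abundance: log-normal for gene and retrotransposon
#' transcripts, a fixed high abundance (the 93rd percentile of the
#' log-normal) for spike-in contigs so the controls are well covered.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param cfg the [SimConfig-class].
#' @return data.frame(txId, txType, relAbundance).
#' @export
simulateExpression <- function(annotation, cfg) {
  withSubstream(cfg@seed, "expression", {
    tx <- mcols(annotation@transcripts)
    ab <- stats::rlnorm(nrow(tx), cfg@expressionMeanlog, cfg@expressionSdlog)
    ab[tx$txType == "spikein"] <-
      exp(cfg@expressionMeanlog + 1.5 * cfg@expressionSdlog)
    data.frame(txId = tx$txId, txType = tx$txType, relAbundance = ab)
  })
}
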