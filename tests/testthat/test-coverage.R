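mkFrags <- function(starts, ends, chromLength = 1000, chrom = "chr1") {
  si <- GenomeInfoDb::Seqinfo(chrom, chromLength)
  gr <- if (!length(starts)) GenomicRanges::GRanges(seqinfo = si)
        else GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends),
                                    seqinfo = si)
  fragmentSet(gr)
}

test_that("bin counting matches interval arithmetic", {
  # empty set -> all-zero track
  empty <- mkFrags(integer(0), integer(0))
  expect_true(all(trackValues(binCoverage(empty))$chr1 == 0))

  # one fragment [31, 175] hits exactly bins 3..17 (0-based)
  t1 <- binCoverage(mkFrags(31, 175), normalize = "count")
  v <- trackValues(t1)$chr1
  expect_equal(which(v > 0), 3:17 + 1L)
  expect_true(all(v[3:17 + 1L] == 1))
})

test_that("RPKM normalisation reproduces the closed form", {
  # 1e6 fragments in total, a bin overlapped by 5 of them, width 10:
  # RPKM = 5 / (10/1000 * 1e6/1e6) = 500
  starts <- c(rep(1L, 5L), rep(501L, 999995L))
  fs <- mkFrags(starts, starts + 7L)
  tr <- binCoverage(fs)
  expect_equal(trackValues(tr)$chr1[1], 500)
  # and the general formula on a small library
  fs2 <- mkFrags(c(1, 3, 5, 201), c(9, 9, 9, 260))
  cnt <- trackValues(binCoverage(fs2, normalize = "count"))$chr1
  rpkm <- trackValues(binCoverage(fs2))$chr1
  expect_equal(rpkm, cnt / (10 / 1000 * 4 / 1e6))
})

test_that("bin counts conserve fragment-bin incidences", {
  fx <- fxSmall()
  cnt <- binCoverage(fx$inp, normalize = "count")
  gr <- fragments(fx$inp)
  blocks <- rtracklayer::blocks(gr)
  perFrag <- vapply(seq_along(gr), function(i) {
    b <- blocks[[i]]
    bins <- unlist(lapply(seq_along(b), function(j)
      seq((GenomicRanges::start(b)[j] - 1L) %/% 10L,
          (GenomicRanges::end(b)[j] - 1L) %/% 10L)))
    length(unique(bins))
  }, 0)
  expect_equal(sum(unlist(trackValues(cnt), use.names = FALSE)),
               sum(perFrag))
})

test_that("m6A signal follows the log2 ratio formula", {
  ip <- toyTrack(c(3, 0, 1, 7))
  inp <- toyTrack(c(1, 7, 1, 7))
  s <- m6aSignal(ip, inp)
  expect_equal(trackValues(s)$chrT, c(1, -3, 0, 0))
  expect_s4_class(s, "SignalTrack")
  # identity and antisymmetry
  expect_true(all(trackValues(m6aSignal(ip, ip))$chrT == 0))
  expect_equal(trackValues(m6aSignal(inp, ip))$chrT,
               -trackValues(s)$chrT)
  # mismatched grids refuse to combine
  expect_error(m6aSignal(ip, toyTrack(c(1, 2), binWidth = 20L, chromLength = 40)), "grid")
})

test_that("TPM normalisation and midpoint assignment behave as specified", {
  ann <- toyAnnotation()
  # single expressed transcript -> TPM 1e6
  one <- fragmentSet(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1101, 1201), width = 100),
    seqinfo = seqinfo(ann)))
  tpm1 <- transcriptTPM(one, ann)
  expect_equal(sum(tpm1$TPM), 1e6)
  # zero counts everywhere -> all TPM 0
  tpm0 <- transcriptTPM(fragmentSet(GenomicRanges::GRanges(
    seqinfo = seqinfo(ann))), ann)
  expect_true(all(tpm0$TPM == 0))
  # counts (10, 10) on lengths (1 kb, 2 kb) -> TPM (666666.7, 333333.3)
  si <- GenomeInfoDb::Seqinfo("chrT", 20000L)
  gr <- function(s, e, st) {
    if (!length(s)) return(GenomicRanges::GRanges(seqinfo = si))
    GenomicRanges::GRanges("chrT", IRanges::IRanges(s, e), strand = st,
                           seqinfo = si)
  }
  tx <- c(gr(1001, 2000, "+"), gr(5001, 7000, "+"))
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    txId = c("t1", "t2"), geneId = c("g1", "g2"), txType = "gene",
    txLen = c(1000L, 2000L), u5Len = NA_integer_, cdsLen = NA_integer_,
    u3Len = NA_integer_)
  ann2 <- new("GenomeAnnotation", seqinfo = si, transcripts = tx,
              exonsByTx = GenomicRanges::GRangesList(
                t1 = gr(1001, 2000, "+"), t2 = gr(5001, 7000, "+")),
              cdsByTx = GenomicRanges::GRangesList(
                t1 = gr(integer(0), integer(0), character(0)),
                t2 = gr(integer(0), integer(0), character(0))),
              utr5ByTx = GenomicRanges::GRangesList(
                t1 = gr(integer(0), integer(0), character(0)),
                t2 = gr(integer(0), integer(0), character(0))),
              utr3ByTx = GenomicRanges::GRangesList(
                t1 = gr(integer(0), integer(0), character(0)),
                t2 = gr(integer(0), integer(0), character(0))),
              stopCodons = gr(integer(0), integer(0), character(0)),
              retroLoci = {
                r <- gr(integer(0), integer(0), character(0))
                S4Vectors::mcols(r) <- S4Vectors::DataFrame(
                  locusId = character(), subfamily = character(),
                  consensusLength = integer())
                r
              })
  frags <- fragmentSet(GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(rep(1101, 10), rep(5101, 10)), width = 100),
    seqinfo = si))
  tpm <- transcriptTPM(frags, ann2)
  expect_equal(tpm$TPM[tpm$txId == "t1"], 2e6 / 3, tolerance = 1e-9)
  expect_equal(tpm$TPM[tpm$txId == "t2"], 1e6 / 3, tolerance = 1e-9)
  expect_equal(sum(tpm$TPM), 1e6)
})

test_that("TPM sums to one million on simulated data", {
  fx <- fxSmall()
  expect_equal(sum(fx$tpm$TPM), 1e6, tolerance = 1e-6)
})

test_that("pairwise correlation has the expected fixed points", {
  ann <- toyAnnotation()
  # windows over txA/txB (bins 100..180) and txC (bins 500..600)
  base <- numeric(2000)
  base[101:180] <- 4
  base[501:600] <- 2
  tA <- toyTrack(base, chromLength = 20000)
  tB <- toyTrack(2 * base, chromLength = 20000)
  r <- pairwiseCorrelation(list(a = tA, self = tA, twice = tB), ann)
  expect_equal(unname(r["a", "self"]), 1)
  expect_equal(unname(r["a", "twice"]), 1)  # scale invariance
  expect_true(isSymmetric(r))

  # anti-monotone pair over three 1-kb windows: (1,2,3) vs (3,2,1)
  si <- GenomeInfoDb::Seqinfo("chrT", 3000L)
  g <- GenomicRanges::GRanges("chrT", IRanges::IRanges(1, 3000),
                              strand = "+", seqinfo = si)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    txId = "t", geneId = "g", txType = "gene", txLen = 3000L,
    u5Len = NA_integer_, cdsLen = NA_integer_, u3Len = NA_integer_)
  empt <- GenomicRanges::GRanges(seqinfo = si)
  annAll <- new("GenomeAnnotation", seqinfo = si, transcripts = g,
                exonsByTx = GenomicRanges::GRangesList(t = g),
                cdsByTx = GenomicRanges::GRangesList(t = empt),
                utr5ByTx = GenomicRanges::GRangesList(t = empt),
                utr3ByTx = GenomicRanges::GRangesList(t = empt),
                stopCodons = empt,
                retroLoci = {
                  r <- empt
                  S4Vectors::mcols(r) <- S4Vectors::DataFrame(
                    locusId = character(), subfamily = character(),
                    consensusLength = integer())
                  r
                })
  up <- toyTrack(rep(c(1, 2, 3), each = 100), chromLength = 3000)
  down <- toyTrack(rep(c(3, 2, 1), each = 100), chromLength = 3000)
  r2 <- pairwiseCorrelation(list(up = up, down = down), annAll)
  expect_equal(unname(r2["up", "down"]), -1)
})

test_that("correlation matrix is positive semidefinite on real tracks", {
  fx <- fxSmall()
  tracks <- lapply(fx$se@samples, binCoverage)
  r <- pairwiseCorrelation(tracks, fx$se@annotation)
  expect_true(isSymmetric(unname(r)))
  expect_true(all(eigen(r, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  expect_true(all(diag(r) == 1))
})

test_that("PCA is deterministic, sign-fixed and needs three samples", {
  fx <- fxSmall()
  tracks <- lapply(fx$se@samples, binCoverage)
  s1 <- m6aSignal(tracks$c1_r1_IP, tracks$c1_r1_input)
  s2 <- m6aSignal(tracks$c1_r2_IP, tracks$c1_r2_input)
  expect_error(pcaM6A(list(s1, s2), fx$se@annotation), "three")
  p <- pcaM6A(list(a = s1, b = s1, c = s2), fx$se@annotation)
  expect_equal(p$coords["a", ], p$coords["b", ])  # duplicated samples
  expect_true(all(p$varianceExplained >= 0 & p$varianceExplained <= 1))
  expect_true(diff(p$varianceExplained) <= 0)
  p2 <- pcaM6A(list(a = s1, b = s1, c = s2), fx$se@annotation)
  expect_identical(p$coords, p2$coords)
})
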