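mkSet <- function(starts, ends, strand = "+", chromLength = 100000) {
  si <- GenomeInfoDb::Seqinfo("chr1", chromLength)
  gr <- if (!length(starts)) GenomicRanges::GRanges(seqinfo = si)
        else GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, ends),
                                    strand = strand, seqinfo = si)
  fragmentSet(gr)
}

test_that("deduplication collapses on the (chrom,start,end,strand) key", {
  fs <- mkSet(c(10, 10, 10), c(100, 100, 100))
  expect_length(deduplicate(fs), 1L)
  fs2 <- mkSet(c(10, 20, 30), c(100, 110, 120))
  expect_length(deduplicate(fs2), 3L)
  # identical coordinates on opposite strands are distinct fragments
  fs3 <- mkSet(c(10, 10), c(100, 100), strand = c("+", "-"))
  expect_length(deduplicate(fs3), 2L)
  # order-independence: shuffled input gives the same canonical result
  fs4 <- mkSet(c(30, 10, 20, 10), c(120, 100, 110, 100))
  fs5 <- mkSet(c(10, 20, 10, 30), c(100, 110, 100, 120))
  expect_identical(as.data.frame(fragments(deduplicate(fs4))),
                   as.data.frame(fragments(deduplicate(fs5))))
})

test_that("Poisson upper tail matches direct series summation", {
  expect_equal(poissonUpperTail(0, 5), 1)
  expect_equal(poissonUpperTail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poissonUpperTail(5, 1), 0.003659847, tolerance = 1e-7)
  expect_error(poissonUpperTail(3, 0), "lambda")
  expect_error(poissonUpperTail(-1, 1), "k")

  directTail <- function(k, lam) {
    if (k == 0) return(1)
    1 - sum(exp(-lam + (0:(k - 1)) * log(lam) - lgamma(1:k)))
  }
  set.seed(42)
  for (i in 1:100) {
    k <- sample(0:50, 1)
    lam <- runif(1, 0.01, 20)
    expect_lt(abs(poissonUpperTail(k, lam) - directTail(k, lam)), 1e-9)
  }
})

test_that("BH q-values match a naive step-up implementation", {
  expect_equal(bhQvalues(0.03), 0.03)
  expect_equal(bhQvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhQvalues(c(0.001, 0.5, 0.9)), c(0.003, 0.75, 0.9))
  expect_error(bhQvalues(c(0.5, 1.2)), "0, 1")

  naiveBH <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
    out <- numeric(n)
    out[o] <- pmin(q, 1)
    out
  }
  set.seed(7)
  for (i in 1:100) {
    p <- runif(sample(2:40, 1))
    expect_equal(bhQvalues(p), naiveBH(p), tolerance = 1e-12)
  }
})

test_that("local lambda follows the window formulas", {
  cfg <- peakCallerConfig()
  # fragments of width 100 aligned to the bin grid overlap exactly 10 bins
  mk <- function(starts0) {
    list(s = sort(starts0), e = sort(starts0 + 100))
  }
  # spike spread uniformly over the 1-kb window around bin 500:
  # lambda_1k dominates the larger windows and equals the hand value
  starts0 <- seq(4510, 5400, by = 10)  # 90 fragments inside [4505, 5505)
  fr <- mk(starts0)
  lam <- localLambda(fr$s, fr$e, bins = 500L, cfg, depthRatio = 1,
                     lambdaBG = 0.01, meanFragBins = 10)
  expect_equal(unname(lam[1, "lambda1000"]), 90 * 10 * 10 / 1000)
  expect_gt(unname(lam[1, "lambda1000"]), unname(lam[1, "lambda5000"]))
  expect_gt(unname(lam[1, "lambda5000"]), unname(lam[1, "lambda10000"]))
  expect_equal(unname(lam[1, "lambdaLocal"]),
               max(lam[1, c("lambdaBG", "lambdaD", "lambda1000",
                            "lambda5000", "lambda10000")]))

  # hand-constructed window counts: 20 fragments inside 1 kb, 20 more in
  # the 5-kb ring, 20 more in the 10-kb ring (depth ratio 1)
  st <- c(seq(4600, 5350, length.out = 20),       # inside [4505, 5505)
          seq(2600, 3300, length.out = 10), seq(6800, 7300, length.out = 10),
          seq(300, 800, length.out = 10), seq(9200, 9700, length.out = 10))
  st <- floor(st / 10) * 10
  fr2 <- mk(st)
  lam2 <- localLambda(fr2$s, fr2$e, bins = 500L, cfg, depthRatio = 1,
                      lambdaBG = 0.01, meanFragBins = 10)
  expect_equal(unname(lam2[1, "lambda1000"]), 20 * 10 * 10 / 1000)
  expect_equal(unname(lam2[1, "lambda5000"]), 40 * 10 * 10 / 5000)
  expect_equal(unname(lam2[1, "lambda10000"]), 60 * 10 * 10 / 10000)

  # uniform coverage: the kilobase-scale windows agree with the genome-wide
  # rate up to the window-edge correction (fragments overlapping the window
  # but centred outside inflate the count by ~fragLen/w), and the
  # fragment-size window's inflation is bounded by (d + fragLen)/d
  u <- mk(seq(0, 99900, by = 10))
  lamBG <- length(u$s) * 10 / (100000 / 10)
  lamU <- localLambda(u$s, u$e, bins = c(2000L, 5000L, 8000L), cfg,
                      depthRatio = 1, lambdaBG = lamBG, meanFragBins = 10)
  for (col in c("lambda1000", "lambda5000", "lambda10000"))
    expect_true(all(abs(lamU[, col] / lamBG - 1) < 0.2))
  expect_true(all(lamU[, "lambdaD"] / lamBG <= (100 + 100) / 100 + 0.1))
  expect_true(all(lamU[, "lambdaLocal"] >= lamBG))
})

test_that("identical IP and input produce no peaks", {
  fx <- fxSmall()
  expect_length(callPeaks(fx$inp, fx$inp, fx$pc), 0L)
})

test_that("called peaks satisfy their structural invariants", {
  fx <- fxSmall()
  pk <- fx$peaks
  expect_gt(length(pk), 0)
  m <- S4Vectors::mcols(pk)
  expect_true(all(m$q < fx$pc@qCutoff))
  expect_true(all(m$q >= m$p))
  expect_true(all(GenomicRanges::width(pk) >= fx$pc@minPeakLength))
  expect_true(all(m$summit >= GenomicRanges::start(pk) &
                    m$summit < GenomicRanges::end(pk)))
  # pairwise disjoint per chromosome
  expect_true(all(GenomicRanges::countOverlaps(pk, pk) == 1))
})

test_that("stricter q cutoffs never add peaks and swapping roles loses them", {
  fx <- fxSmall()
  stricter <- fx$pc
  stricter@qCutoff <- 1e-5
  expect_lte(length(callPeaks(fx$ip, fx$inp, stricter)), length(fx$peaks))
  swapped <- callPeaks(fx$inp, fx$ip, fx$pc)
  expect_lt(length(swapped), length(fx$peaks))
})

test_that("degenerate caller inputs are handled explicitly", {
  empty <- mkSet(integer(0), integer(0))
  some <- mkSet(c(100, 300), c(250, 450))
  expect_warning(res <- callPeaks(empty, some), "empty IP")
  expect_length(res, 0L)
  expect_error(peakCallerConfig(qCutoff = 0), "qCutoff")
  expect_error(peakCallerConfig(effectiveSize = -1), "effectiveSize")
})
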