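test_that("config validation rejects out-of-range parameters", {
  expect_error(simConfig(stopCodonBias = 1.5), "stopCodonBias")
  expect_error(simConfig(ipEnrichmentFactor = 0.5), "ipEnrichmentFactor")
  expect_error(simConfig(backgroundBindingRate = -0.1),
               "backgroundBindingRate")
  expect_error(simConfig(baseFreqs = c(A = 1, C = 0, G = 0, T = 0.5)),
               "baseFreqs")
})

test_that("annotation generation is deterministic and structurally sound", {
  cfg <- simConfig(seed = 3L, nGenes = 10L, nChroms = 1L,
                   chromLength = 150000L)
  g1 <- generateAnnotation(cfg)
  g2 <- generateAnnotation(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(serialize(g1$annotation, NULL, version = 2),
                   serialize(g2$annotation, NULL, version = 2))

  ann <- g1$annotation
  tx <- transcripts(ann)
  gene <- tx[S4Vectors::mcols(tx)$txType == "gene"]
  expect_length(gene, 10L)
  expect_setequal(unique(as.character(GenomicRanges::strand(gene))),
                  c("+", "-"))
  m <- S4Vectors::mcols(gene)
  expect_true(all(m$cdsLen %% 3 == 0))
  expect_true(all(m$u5Len > 0 & m$cdsLen > 0 & m$u3Len > 0))
  expect_true(all(m$txLen == m$u5Len + m$cdsLen + m$u3Len))
  # stop codon = 3' terminus of the CDS, checked in transcript coordinates
  for (i in seq_along(gene)) {
    id <- m$txId[i]
    tab <- m6Akit:::txExonTable(ann, id)
    want <- m6Akit:::mapTxInterval(m$u5Len[i] + m$cdsLen[i] - 3L,
                                   m$u5Len[i] + m$cdsLen[i], tab,
                                   tab$strand)
    sc <- ann@stopCodons[id]
    expect_equal(min(want[, 1]) + 1L, GenomicRanges::start(sc)[1])
    expect_equal(max(want[, 2]), GenomicRanges::end(sc)[1])
  }
  # retro subfamilies placed at the requested counts and lengths
  rl <- retroLoci(ann)
  expect_equal(sum(S4Vectors::mcols(rl)$subfamily == "MTA"), 20L)
  expect_true(all(S4Vectors::mcols(rl)$consensusLength[
    S4Vectors::mcols(rl)$subfamily == "MTA"] == 500L))
  expect_true(all(GenomicRanges::width(rl) >=
                    0.9 * S4Vectors::mcols(rl)$consensusLength))
})

test_that("genome capacity overflow raises a sizing error", {
  expect_error(generateAnnotation(simConfig(nGenes = 100L, nChroms = 1L,
                                            chromLength = 30000L)),
               "capacity")
})

test_that("every planted site sits on an RRACH A on its transcript strand", {
  fx <- fxSmall()
  checks <- siteMotifCheck(fx$se@truth, fx$se@genome)
  expect_true(all(checks))
  expect_gt(length(checks), 0)
})

test_that("stop-codon bias limit cases and binomial behaviour hold", {
  # limit: bias 1 puts every gene site within 400 bp of a stop codon
  cfg <- smallConfig(seed = 21L, stopCodonBias = 1)
  gen <- generateAnnotation(cfg)
  tr <- plantSites(gen$annotation, gen$genome, cfg)
  s <- truthSites(tr)
  s <- s[S4Vectors::mcols(s)$kind == "gene"]
  sc <- gen$annotation@stopCodons[S4Vectors::mcols(s)$txId]
  d <- pmax(0, pmax(GenomicRanges::start(sc) - GenomicRanges::start(s),
                    GenomicRanges::start(s) - GenomicRanges::end(sc)))
  expect_true(all(d <= 400))

  # bias 0.7 with n = 200 (study defaults): proximal count within the
  # binomial 95% envelope [120, 160]
  fx <- fxDefault()
  s <- truthSites(fx$se@truth)
  s <- s[S4Vectors::mcols(s)$kind == "gene"]
  expect_length(s, 200L)
  sc <- fx$se@annotation@stopCodons[S4Vectors::mcols(s)$txId]
  d <- pmax(0, pmax(GenomicRanges::start(sc) - GenomicRanges::start(s),
                    GenomicRanges::start(s) - GenomicRanges::end(sc)))
  expect_gte(sum(d <= 400), 120)
  expect_lte(sum(d <= 400), 160)

  # zero sites is a valid (empty) truth
  cfg0 <- smallConfig(seed = 22L, nM6aSites = 0L)
  gen0 <- generateAnnotation(cfg0)
  tr0 <- plantSites(gen0$annotation, gen0$genome, cfg0)
  expect_equal(sum(S4Vectors::mcols(truthSites(tr0))$kind == "gene"), 0L)

  # asking for more sites than the motif pool supports fails informatively
  cfgBig <- smallConfig(seed = 23L, nM6aSites = 100000L)
  genBig <- generateAnnotation(cfgBig)
  expect_error(plantSites(genBig$annotation, genBig$genome, cfgBig),
               "RRACH")
})

test_that("planted sites within a condition respect the minimum spacing", {
  fx <- fxDefault()
  s <- truthSites(fx$se@truth)
  s <- s[S4Vectors::mcols(s)$kind == "gene"]
  bychrom <- split(GenomicRanges::start(s),
                   as.character(GenomicRanges::seqnames(s)))
  gaps <- unlist(lapply(bychrom, function(p) diff(sort(p))))
  expect_true(all(gaps >= fx$cfg@minSiteSpacing))
})

test_that("fragment simulation is seed-deterministic", {
  fx <- fxSmall()
  again <- simulateFragments(fx$se@annotation, fx$se@truth,
                             fx$se@expression, fx$cfg, role = "IP")
  expect_identical(as.data.frame(fragments(again)),
                   as.data.frame(fragments(fx$se@samples$c1_r1_IP)))
})

test_that("input fragment counts follow expression x length weights", {
  fx <- fxSmall()
  tpm <- transcriptTPM(fx$se@samples$c1_r1_input, fx$se@annotation)
  w <- fx$se@expression$relAbundance[match(tpm$txId,
                                           fx$se@expression$txId)]
  lens <- S4Vectors::mcols(transcripts(fx$se@annotation))$txLen[
    match(tpm$txId, S4Vectors::mcols(transcripts(fx$se@annotation))$txId)]
  w <- w * lens
  gof <- suppressWarnings(stats::chisq.test(tpm$count, p = w / sum(w)))
  expect_gt(gof$p.value, 0.001)
})

test_that("IP enrichment concentrates coverage on planted sites", {
  fx <- fxDefault()
  sig <- fx$sig1
  s <- truthSites(fx$se@truth)
  s <- s[S4Vectors::mcols(s)$kind == "gene"]
  siteVal <- vapply(seq_along(s), function(i) {
    ch <- as.character(GenomicRanges::seqnames(s))[i]
    sig@values[[ch]][(GenomicRanges::start(s)[i] - 1L) %/% 10L + 1L]
  }, 0)
  # matched unmethylated positions: same transcripts, shifted 500 bp
  off <- GenomicRanges::shift(s, 500L)
  inb <- GenomicRanges::start(off) <=
    GenomeInfoDb::seqlengths(seqinfo(sig))[
      as.character(GenomicRanges::seqnames(off))]
  s <- s[inb]; off <- off[inb]; siteVal <- siteVal[inb]
  offVal <- vapply(seq_along(off), function(i) {
    ch <- as.character(GenomicRanges::seqnames(off))[i]
    sig@values[[ch]][(GenomicRanges::start(off)[i] - 1L) %/% 10L + 1L]
  }, 0)
  expect_gte(length(siteVal), 50)
  expect_gt(mean(siteVal - offVal), 0)
  expect_gt(mean(siteVal > offVal), 0.8)
})

test_that("pure-IP limit retains only site-covering fragments", {
  cfg <- smallConfig(seed = 31L, backgroundBindingRate = 0,
                     stoichiometryRange = c(1, 1),
                     nFragmentsPerSample = 5000L)
  gen <- generateAnnotation(cfg)
  tr <- plantSites(gen$annotation, gen$genome, cfg)
  expr <- simulateExpression(gen$annotation, cfg)
  ip <- simulateFragments(gen$annotation, tr, expr, cfg, role = "IP")
  hits <- GenomicRanges::countOverlaps(fragments(ip), truthSites(tr),
                                       ignore.strand = TRUE)
  expect_true(all(hits > 0))
})
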