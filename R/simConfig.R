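#' Build a simulation configuration
#'
#' Constructor for [SimConfig-class] with the defaults that define the
#' standard simulated study: a ~3-Mb toy genome carrying 300 spliced
#' protein-coding gene models, 200 m6A sites per condition planted on RRACH
#' adenosines with a 0.7 stop-codon-proximal bias and stoichiometry drawn
#' uniformly from \[0.5, 1\], 8-fold IP enrichment over a 5% nonspecific
#' background at 2e5 fragments per library, one m6A-modified (GLuc) and one
#' unmodified (CLuc) spike-in contig, and a methylated (MTA) versus an
#' unmethylated (L1) retrotransposon subfamily.
#'
#' The genome base composition is deliberately pyrimidine-rich (A = G = 0.12,
#' C = T = 0.38) so that the RRACH consensus occurs at a controlled background
#' rate of roughly one per kilobase; with a uniform composition nearly every
#' 400-bp window contains the pentamer and window-level motif statistics
#' carry no information.
#'
#' @param seed integer master seed.
#' @param nChroms,chromLength genome shape.
#' @param nGenes number of gene models.
#' @param utr5Range,cdsRange,utr3Range,exonsPerGene,intronRange gene
#'   structure ranges (bp; exon count).
#' @param baseFreqs named A/C/G/T composition summing to 1.
#' @param expressionMeanlog,expressionSdlog log-normal expression model.
#' @param nM6aSites,stopCodonBias,stoichiometryRange,minSiteSpacing planted
#'   site model.
#' @param fragmentLengthMean,fragmentLengthSd,nFragmentsPerSample library
#'   model.
#' @param ipEnrichmentFactor,backgroundBindingRate IP selection model.
#' @param spikeinLengths,spikeinModified named spike-in contigs.
#' @param retroSubfamilies data.frame(name, consensusLength, nLoci,
#'   methylated).
#' @param conditions,replicates experiment layout.
#' @param qpcrIntercept,qpcrCtSd qPCR Ct model.
#' @return a validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 20, nM6aSites = 10,
#'                  nFragmentsPerSample = 5000)
#' @export
simConfig <- function(seed = 1L,
                      nChroms = 4L,
                      chromLength = 750000L,
                      nGenes = 300L,
                      utr5Range = c(100L, 300L),
                      cdsRange = c(300L, 1500L),
                      utr3Range = c(250L, 800L),
                      exonsPerGene = c(1L, 3L),
                      intronRange = c(200L, 800L),
                      baseFreqs = c(A = 0.12, C = 0.38, G = 0.12, T = 0.38),
                      expressionMeanlog = 1,
                      expressionSdlog = 1,
                      nM6aSites = 200L,
                      stopCodonBias = 0.7,
                      stoichiometryRange = c(0.5, 1),
                      minSiteSpacing = 600L,
                      fragmentLengthMean = 150,
                      fragmentLengthSd = 30,
                      nFragmentsPerSample = 200000L,
                      ipEnrichmentFactor = 8,
                      backgroundBindingRate = 0.05,
                      spikeinLengths = c(GLuc = 550L, CLuc = 550L),
                      spikeinModified = c(GLuc = TRUE, CLuc = FALSE),
                      retroSubfamilies = data.frame(
                        name = c("MTA", "L1"),
                        consensusLength = c(500L, 1500L),
                        nLoci = c(20L, 20L),
                        methylated = c(TRUE, FALSE)),
                      conditions = 1L,
                      replicates = 2L,
                      qpcrIntercept = 30,
                      qpcrCtSd = 0.2) {
  new("SimConfig",
      seed = as.integer(seed), nChroms = as.integer(nChroms),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      utr5Range = as.integer(utr5Range), cdsRange = as.integer(cdsRange),
      utr3Range = as.integer(utr3Range),
      exonsPerGene = as.integer(exonsPerGene),
      intronRange = as.integer(intronRange),
      baseFreqs = baseFreqs,
      expressionMeanlog = expressionMeanlog,
      expressionSdlog = expressionSdlog,
      nM6aSites = as.integer(nM6aSites), stopCodonBias = stopCodonBias,
      stoichiometryRange = as.numeric(stoichiometryRange),
      minSiteSpacing = as.integer(minSiteSpacing),
      fragmentLengthMean = fragmentLengthMean,
      fragmentLengthSd = fragmentLengthSd,
      nFragmentsPerSample = as.integer(nFragmentsPerSample),
      ipEnrichmentFactor = ipEnrichmentFactor,
      backgroundBindingRate = backgroundBindingRate,
      spikeinLengths = vapply(spikeinLengths, as.integer, 0L),
      spikeinModified = spikeinModified,
      retroSubfamilies = retroSubfamilies,
      conditions = as.integer(conditions),
      replicates = as.integer(replicates),
      qpcrIntercept = qpcrIntercept, qpcrCtSd = qpcrCtSd)
}

#' Construct a FragmentSet
#'
#' @param fragments `GRanges` of fragment spans; a `blocks` metadata column
#'   (`IRangesList` of 1-based block ranges relative to each span start) is
#'   added as single whole-span blocks when absent.
#' @param sampleId sample identifier.
#' @param role `"IP"` or `"input"`.
#' @param condition,replicate integers.
#' @return a [FragmentSet-class].
#' @export
fragmentSet <- function(fragments, sampleId = "sample", role = "input",
                        condition = 1L, replicate = 1L) {
  if (!"blocks" %in% colnames(mcols(fragments)))
    mcols(fragments)$blocks <- IRanges::relist(
      IRanges(1L, width = width(fragments)),
      IRanges::PartitioningByEnd(seq_along(fragments)))
  new("FragmentSet", sampleId = as.character(sampleId), role = role,
      condition = as.integer(condition), replicate = as.integer(replicate),
      fragments = fragments)
}
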