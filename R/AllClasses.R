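#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width strand
#' @importFrom IRanges IRanges IRangesList
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqlevels seqinfo
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic MeRIP-seq experiment generator. The defaults
#' (see [simConfig()]) describe the standard simulated study: ~300 genes on a
#' few megabases, 200 planted m6A sites at RRACH motifs with a 0.7 stop-codon
#' bias and stoichiometry in \[0.5, 1\], 8-fold IP enrichment over a 5%
#' nonspecific background, 2e5 fragments per library, one modified and one
#' unmodified spike-in contig, and a methylated vs an unmethylated
#' retrotransposon subfamily.
#'
#' @slot seed integer master seed; all stages draw from named substreams of it.
#' @slot nChroms,chromLength integer; number and length (bp) of chromosomes.
#' @slot nGenes integer number of protein-coding gene models.
#' @slot utr5Range,cdsRange,utr3Range integer(2) length ranges in bp (CDS is
#'   rounded to a codon multiple).
#' @slot exonsPerGene integer(2) range of exon counts per transcript.
#' @slot intronRange integer(2) intron length range in bp.
#' @slot baseFreqs named numeric(4) A/C/G/T genome composition.
#' @slot expressionMeanlog,expressionSdlog log-normal expression parameters.
#' @slot nM6aSites integer planted sites per condition.
#' @slot stopCodonBias probability that a site is drawn from the pool within
#'   400 bp of a stop codon.
#' @slot stoichiometryRange numeric(2) uniform range of per-site stoichiometry.
#' @slot minSiteSpacing integer minimum genomic distance (bp) between planted
#'   sites of one condition.
#' @slot fragmentLengthMean,fragmentLengthSd fragment length model (bp,
#'   normal truncated at 30 bp).
#' @slot nFragmentsPerSample integer library size after renormalisation.
#' @slot ipEnrichmentFactor fold enrichment (>= 1) of a fully methylated
#'   fragment in the IP.
#' @slot backgroundBindingRate nonspecific IP retention weight in \[0, 1\].
#' @slot spikeinLengths named integer, spike-in contig lengths (bp).
#' @slot spikeinModified named logical, which spike-ins carry m6A.
#' @slot retroSubfamilies data.frame(name, consensusLength, nLoci, methylated).
#' @slot conditions,replicates integers.
#' @slot qpcrIntercept,qpcrCtSd qPCR Ct model: Ct = intercept - log2(conc) +
#'   N(0, sd).
#'
#' @seealso [simConfig()], [simulateExperiment()]
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  nChroms = "integer",
  chromLength = "integer",
  nGenes = "integer",
  utr5Range = "integer",
  cdsRange = "integer",
  utr3Range = "integer",
  exonsPerGene = "integer",
  intronRange = "integer",
  baseFreqs = "numeric",
  expressionMeanlog = "numeric",
  expressionSdlog = "numeric",
  nM6aSites = "integer",
  stopCodonBias = "numeric",
  stoichiometryRange = "numeric",
  minSiteSpacing = "integer",
  fragmentLengthMean = "numeric",
  fragmentLengthSd = "numeric",
  nFragmentsPerSample = "integer",
  ipEnrichmentFactor = "numeric",
  backgroundBindingRate = "numeric",
  spikeinLengths = "integer",
  spikeinModified = "logical",
  retroSubfamilies = "data.frame",
  conditions = "integer",
  replicates = "integer",
  qpcrIntercept = "numeric",
  qpcrCtSd = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- function(x, nm) if (any(x <= 0)) sprintf("'%s' must be > 0", nm)
  msg <- c(msg,
    pos(object@nChroms, "nChroms"), pos(object@chromLength, "chromLength"),
    pos(object@nGenes, "nGenes"), pos(object@utr5Range, "utr5Range"),
    pos(object@cdsRange, "cdsRange"), pos(object@utr3Range, "utr3Range"),
    pos(object@fragmentLengthMean, "fragmentLengthMean"))
  if (object@stopCodonBias < 0 || object@stopCodonBias > 1)
    msg <- c(msg, "'stopCodonBias' must be in [0, 1]")
  if (object@backgroundBindingRate < 0 || object@backgroundBindingRate > 1)
    msg <- c(msg, "'backgroundBindingRate' must be in [0, 1]")
  if (any(object@stoichiometryRange < 0) || any(object@stoichiometryRange > 1))
    msg <- c(msg, "'stoichiometryRange' must be within [0, 1]")
  if (object@ipEnrichmentFactor < 1)
    msg <- c(msg, "'ipEnrichmentFactor' must be >= 1")
  if (object@nM6aSites < 0)
    msg <- c(msg, "'nM6aSites' must be >= 0")
  if (abs(sum(object@baseFreqs) - 1) > 1e-8 ||
      !identical(names(object@baseFreqs), c("A", "C", "G", "T")))
    msg <- c(msg, "'baseFreqs' must be named A/C/G/T and sum to 1")
  if (length(object@spikeinLengths) != length(object@spikeinModified) ||
      !identical(names(object@spikeinLengths), names(object@spikeinModified)))
    msg <- c(msg, "'spikeinLengths' and 'spikeinModified' must share names")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## GenomeAnnotation
## ---------------------------------------------------------------------------

#' Genome annotation container
#'
#' Gene models with 5'UTR/CDS/3'UTR structure, spike-in contigs carried as
#' single-exon transcripts, and retrotransposon loci, all against one
#' `Seqinfo`. Transcript-level structure is held as `GRangesList`s named by
#' transcript id; `transcripts` holds the genomic spans with `txId`, `geneId`
#' and `txType` (`"gene"`, `"spikein"` or `"retro"`) metadata columns.
#'
#' @slot seqinfo `Seqinfo` for all chromosomes (incl. spike-in contigs).
#' @slot transcripts `GRanges` of transcript spans.
#' @slot exonsByTx,cdsByTx,utr5ByTx,utr3ByTx `GRangesList` keyed by txId
#'   (cds/utr lists are empty for non-coding transcripts).
#' @slot stopCodons `GRanges` of the 3-bp stop codons, named by txId.
#' @slot retroLoci `GRanges` with `subfamily` and `consensusLength` columns.
#'
#' @export
setClass("GenomeAnnotation", representation(
  seqinfo = "Seqinfo",
  transcripts = "GRanges",
  exonsByTx = "GRangesList",
  cdsByTx = "GRangesList",
  utr5ByTx = "GRangesList",
  utr3ByTx = "GRangesList",
  stopCodons = "GRanges",
  retroLoci = "GRanges"
))

setValidity("GenomeAnnotation", function(object) {
  tx <- object@transcripts
  need <- c("txId", "geneId", "txType")
  if (!all(need %in% colnames(mcols(tx))))
    return("transcripts must carry txId/geneId/txType metadata columns")
  if (anyDuplicated(mcols(tx)$txId))
    return("duplicated transcript ids")
  if (!all(mcols(tx)$txId %in% names(object@exonsByTx)))
    return("every transcript needs an exonsByTx entry")
  TRUE
})

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' Ground-truth registry of planted m6A sites
#'
#' The registry the simulator writes and against which peak calls are scored.
#' `sites` is a `GRanges` of single methylated adenosines (the A of an RRACH
#' pentamer on the transcript strand) with metadata columns `txId`, `txPos`
#' (0-based transcript coordinate of the A), `stoichiometry`, `condition`
#' (integer; `NA` for sites shared by all conditions) and `kind`
#' (`"gene"`, `"spikein"`, `"retro"`).
#'
#' @slot sites `GRanges` as described above.
#' @slot spikeinStatus named logical: is each spike-in contig modified.
#' @slot retroTruth named logical: is each retro subfamily methylated.
#'
#' @export
setClass("SyntheticTruth", representation(
  sites = "GRanges",
  spikeinStatus = "logical",
  retroTruth = "logical"
))

## ---------------------------------------------------------------------------
## FragmentSet
## ---------------------------------------------------------------------------

#' A sample's aligned fragments
#'
#' One library's aligned, deduplicated fragments -- the universal input
#' currency of the pipeline. Fragments are stored as a `GRanges` of genomic
#' spans with a `blocks` metadata column (`IRangesList`, 1-based ranges
#' relative to the span start, the `rtracklayer` BED12 convention) describing
#' the exonic footprint of spliced fragments.
#'
#' @slot sampleId character.
#' @slot role `"IP"` or `"input"`.
#' @slot condition,replicate integers.
#' @slot fragments `GRanges` with `blocks` column.
#'
#' @seealso [fragmentSet()], [readFragmentsBED()], [writeFragmentsBED()]
#' @export
setClass("FragmentSet", representation(
  sampleId = "character",
  role = "character",
  condition = "integer",
  replicate = "integer",
  fragments = "GRanges"
))

setValidity("FragmentSet", function(object) {
  if (!object@role %in% c("IP", "input"))
    return("role must be 'IP' or 'input'")
  fr <- object@fragments
  if (!"blocks" %in% colnames(mcols(fr)))
    return("fragments must carry a 'blocks' IRangesList column")
  sl <- seqlengths(seqinfo(fr))
  if (length(fr) && !all(is.na(sl))) {
    lim <- sl[as.character(seqnames(fr))]
    ok <- is.na(lim) | (start(fr) >= 1 & end(fr) <= lim)
    if (!all(ok)) return("fragments outside chromosome bounds")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## BinnedTrack / SignalTrack
## ---------------------------------------------------------------------------

#' Fixed-width binned genome track
#'
#' Per-bin values over a genome on a fixed grid (bin b covers
#' `[b*binWidth, (b+1)*binWidth)` in 0-based genomic coordinates). The value
#' is either the fragment-overlap count per bin (`kind = "count"`), its RPKM
#' normalisation (`kind = "rpkm"`), or the log2 m6A signal
#' (`kind = "signal"`, see [m6aSignal()]).
#'
#' @slot binWidth integer bin width in bp.
#' @slot values named list of per-chromosome numeric vectors, each of length
#'   `ceiling(seqlength / binWidth)`.
#' @slot seqinfo `Seqinfo`.
#' @slot totalFragments numeric library size backing the normalisation.
#' @slot kind `"count"`, `"rpkm"` or `"signal"`.
#'
#' @seealso [binCoverage()], [m6aSignal()], [writeBedGraph()]
#' @export
setClass("BinnedTrack", representation(
  binWidth = "integer",
  values = "list",
  seqinfo = "Seqinfo",
  totalFragments = "numeric",
  kind = "character"
))

setValidity("BinnedTrack", function(object) {
  if (object@binWidth <= 0L) return("binWidth must be > 0")
  if (!object@kind %in% c("count", "rpkm", "signal"))
    return("kind must be 'count', 'rpkm' or 'signal'")
  sl <- seqlengths(object@seqinfo)
  if (!identical(sort(names(object@values)), sort(names(sl))))
    return("values must be named by the seqinfo chromosomes")
  expect <- ceiling(sl / object@binWidth)
  got <- vapply(object@values, length, 0L)[names(sl)]
  if (!all(got == expect))
    return("value vector lengths must be ceiling(seqlength/binWidth)")
  if (object@kind != "signal" && any(unlist(object@values, use.names = FALSE) < 0))
    return("coverage tracks must be non-negative")
  TRUE
})

#' @describeIn BinnedTrack-class log2((IP RPKM + 1)/(input RPKM + 1)) signal
#'   track; records the IP and input sample ids it was derived from.
#' @slot ipId,inputId sample ids of the source tracks.
#' @export
setClass("SignalTrack", contains = "BinnedTrack", representation(
  ipId = "character",
  inputId = "character"
))

## ---------------------------------------------------------------------------
## SimulatedExperiment
## ---------------------------------------------------------------------------

#' A complete simulated MeRIP-seq experiment
#'
#' Bundles everything one draw of the generator produces: genome, annotation,
#' truth registry, expression table and the IP/input fragment libraries for
#' every condition x replicate.
#'
#' @slot config the `SimConfig` used.
#' @slot genome `DNAStringSet`.
#' @slot annotation `GenomeAnnotation`.
#' @slot truth `SyntheticTruth`.
#' @slot expression data.frame(txId, txType, relAbundance).
#' @slot samples named list of `FragmentSet`s (names like `c1_r1_IP`).
#'
#' @seealso [simulateExperiment()]
#' @export
setClass("SimulatedExperiment", representation(
  config = "SimConfig",
  genome = "ANY",
  annotation = "GenomeAnnotation",
  truth = "SyntheticTruth",
  expression = "data.frame",
  samples = "list"
))
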