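#' @include AllClasses.R
NULL

#' Accessors for m6Akit classes
#'
#' Small accessor generics: `fragments()` returns the fragment `GRanges` of a
#' [FragmentSet-class], `sampleRole()` its IP/input role, `sampleId()` its id;
#' `binWidth()`, `trackValues()`, `trackKind()` and `totalFragments()` expose
#' a [BinnedTrack-class]; `truthSites()` the site `GRanges` of a
#' [SyntheticTruth-class]; `transcripts()`, `exonsByTx()` and `retroLoci()`
#' the slots of a [GenomeAnnotation-class].
#'
#' @param x the object.
#' @return the slot value.
#' @name accessors
#' @aliases fragments sampleRole sampleId binWidth trackValues trackKind
#'   totalFragments truthSites transcripts exonsByTx retroLoci
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("sampleRole", function(x) standardGeneric("sampleRole"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))
#' @rdname accessors
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname accessors
#' @export
setGeneric("trackKind", function(x) standardGeneric("trackKind"))
#' @rdname accessors
#' @export
setGeneric("totalFragments", function(x) standardGeneric("totalFragments"))
#' @rdname accessors
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))
#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))
#' @rdname accessors
#' @export
setGeneric("exonsByTx", function(x) standardGeneric("exonsByTx"))
#' @rdname accessors
#' @export
setGeneric("retroLoci", function(x) standardGeneric("retroLoci"))

#' @rdname accessors
setMethod("fragments", "FragmentSet", function(x) x@fragments)
#' @rdname accessors
setMethod("sampleRole", "FragmentSet", function(x) x@role)
#' @rdname accessors
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("binWidth", "BinnedTrack", function(x) x@binWidth)
#' @rdname accessors
setMethod("trackValues", "BinnedTrack", function(x) x@values)
#' @rdname accessors
setMethod("trackKind", "BinnedTrack", function(x) x@kind)
#' @rdname accessors
setMethod("totalFragments", "BinnedTrack", function(x) x@totalFragments)
#' @rdname accessors
setMethod("truthSites", "SyntheticTruth", function(x) x@sites)
#' @rdname accessors
setMethod("transcripts", "GenomeAnnotation", function(x) x@transcripts)
#' @rdname accessors
setMethod("exonsByTx", "GenomeAnnotation", function(x) x@exonsByTx)
#' @rdname accessors
setMethod("retroLoci", "GenomeAnnotation", function(x) x@retroLoci)

#' @importFrom GenomeInfoDb seqinfo
#' @export
setMethod("seqinfo", "GenomeAnnotation", function(x) x@seqinfo)
#' @export
setMethod("seqinfo", "BinnedTrack", function(x) x@seqinfo)
#' @export
setMethod("seqinfo", "FragmentSet", function(x) seqinfo(x@fragments))

#' @export
setMethod("length", "FragmentSet", function(x) length(x@fragments))

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf("FragmentSet '%s' (%s, condition %d, replicate %d): %d fragments on %d seqs\n",
              object@sampleId, object@role, object@condition,
              object@replicate, length(object@fragments),
              length(seqlevels(seqinfo(object)))))
})

setMethod("show", "BinnedTrack", function(object) {
  cat(sprintf("%s [%s]: %d-bp bins over %d seqs (%s bins), %g fragments\n",
              class(object), object@kind, object@binWidth,
              length(object@values),
              format(sum(vapply(object@values, length, 0L)), big.mark = ","),
              object@totalFragments))
})

setMethod("show", "GenomeAnnotation", function(object) {
  tt <- table(mcols(object@transcripts)$txType)
  cat(sprintf("GenomeAnnotation: %d seqs; transcripts: %s; %d retro loci\n",
              length(seqlevels(object@seqinfo)),
              paste(sprintf("%s=%d", names(tt), as.integer(tt)), collapse = ", "),
              length(object@retroLoci)))
})

setMethod("show", "SyntheticTruth", function(object) {
  kk <- table(mcols(object@sites)$kind)
  cat(sprintf("SyntheticTruth: %d planted sites (%s); spike-ins: %s\n",
              length(object@sites),
              paste(sprintf("%s=%d", names(kk), as.integer(kk)), collapse = ", "),
              paste(sprintf("%s=%s", names(object@spikeinStatus),
                            ifelse(object@spikeinStatus, "m6A", "unmod")),
                    collapse = ", ")))
})

setMethod("show", "SimulatedExperiment", function(object) {
  cat(sprintf("SimulatedExperiment: seed %d, %d condition(s) x %d replicate(s), %d libraries\n",
              object@config@seed, object@config@conditions,
              object@config@replicates, length(object@samples)))
  show(object@annotation)
  show(object@truth)
})
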