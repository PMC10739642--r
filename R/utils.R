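## Internal helpers: named RNG substreams and small interval utilities.

## All randomness in the package flows from one integer master seed through
## named substreams, so each stage (annotation, sites, fragments of a given
## library, qPCR, background windows, subsampling) is independently
## reproducible. The substream seed is a deterministic hash of (seed, name),
## kept below 2^31 - 1.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

## Evaluate expr under a substream RNG state, restoring the caller's state.
withSubstream <- function(seed, name, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  expr
}

## Integer sample from an inclusive range vector c(lo, hi).
sampleRange <- function(n, range) {
  if (range[1] == range[2]) rep.int(as.integer(range[1]), n)
  else as.integer(range[1] + floor(runif(n) * (range[2] - range[1] + 1)))
}

## First/last 10-bp-grid bin (0-based) overlapped by 0-based half-open [s, e).
binIndex <- function(pos, binWidth) as.integer(pos %/% binWidth)

## Map a set of 0-based half-open genomic intervals to the 0-based bins they
## overlap, returning (index of interval, bin) pairs as a two-column list.
intervalBins <- function(start0, end0, binWidth) {
  b0 <- binIndex(start0, binWidth)
  b1 <- binIndex(end0 - 1L, binWidth)
  n <- b1 - b0 + 1L
  list(interval = rep.int(seq_along(start0), n),
       bin = b0[rep.int(seq_along(start0), n)] +
         (sequence(n) - 1L))
}

## Named per-chromosome zero vectors on the bin grid.
emptyBins <- function(seqinfo, binWidth) {
  sl <- seqlengths(seqinfo)
  lapply(stats::setNames(as.list(ceiling(sl / binWidth)), names(sl)),
         function(n) numeric(n))
}

stopifnotScalar <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", nm), call. = FALSE)
}
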