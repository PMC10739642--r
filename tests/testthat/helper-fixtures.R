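# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

smallConfig <- function(seed = 11L, nM6aSites = 15L,
                        nFragmentsPerSample = 20000L, ...) {
  simConfig(seed = seed, nGenes = 25L, nChroms = 1L, chromLength = 300000L,
            nM6aSites = nM6aSites,
            nFragmentsPerSample = nFragmentsPerSample, ...)
}

# Small simulated experiment + one replicate's peak call, for unit tests.
fxSmall <- function() {
  if (is.null(.fx$small)) {
    cfg <- smallConfig()
    se <- simulateExperiment(cfg)
    pc <- peakCallerConfig(
      effectiveSize = effectiveTranscriptomeSize(se@annotation))
    ip <- deduplicate(se@samples$c1_r1_IP)
    inp <- deduplicate(se@samples$c1_r1_input)
    peaks <- callPeaks(ip, inp, pc)
    tpm <- transcriptTPM(inp, se@annotation)
    .fx$small <- list(cfg = cfg, se = se, pc = pc, ip = ip, inp = inp,
                      peaks = peaks, tpm = tpm)
  }
  .fx$small
}

# The standard study conditions (simConfig defaults, seed 1): both
# replicates called, plus coverage/signal tracks.
fxDefault <- function() {
  if (is.null(.fx$def)) {
    cfg <- simConfig(seed = 1L)
    se <- simulateExperiment(cfg)
    ann <- se@annotation
    pc <- peakCallerConfig(effectiveSize = effectiveTranscriptomeSize(ann))
    ip1 <- deduplicate(se@samples$c1_r1_IP)
    inp1 <- deduplicate(se@samples$c1_r1_input)
    ip2 <- deduplicate(se@samples$c1_r2_IP)
    inp2 <- deduplicate(se@samples$c1_r2_input)
    peaks1 <- callPeaks(ip1, inp1, pc)
    peaks2 <- callPeaks(ip2, inp2, pc)
    tpm <- transcriptTPM(inp1, ann)
    tracks <- lapply(se@samples, binCoverage)
    sig1 <- m6aSignal(tracks$c1_r1_IP, tracks$c1_r1_input)
    sig2 <- m6aSignal(tracks$c1_r2_IP, tracks$c1_r2_input)
    .fx$def <- list(cfg = cfg, se = se, pc = pc,
                    ip1 = ip1, inp1 = inp1, ip2 = ip2, inp2 = inp2,
                    peaks1 = peaks1, peaks2 = peaks2, tpm = tpm,
                    tracks = tracks, sig1 = sig1, sig2 = sig2)
  }
  .fx$def
}

# Two conditions with disjoint planted site sets (defaults otherwise).
fxTwoCond <- function() {
  if (is.null(.fx$two)) {
    cfg <- simConfig(seed = 1L, conditions = 2L)
    se <- simulateExperiment(cfg)
    tracks <- lapply(se@samples, binCoverage)
    sigs <- list(
      c1_r1 = m6aSignal(tracks$c1_r1_IP, tracks$c1_r1_input),
      c1_r2 = m6aSignal(tracks$c1_r2_IP, tracks$c1_r2_input),
      c2_r1 = m6aSignal(tracks$c2_r1_IP, tracks$c2_r1_input),
      c2_r2 = m6aSignal(tracks$c2_r2_IP, tracks$c2_r2_input))
    .fx$two <- list(cfg = cfg, se = se, sigs = sigs)
  }
  .fx$two
}

# Manual BinnedTrack on a single toy chromosome.
toyTrack <- function(values, kind = "rpkm", chromLength = length(values) * 10,
                     binWidth = 10L, total = 1000) {
  new("BinnedTrack", binWidth = as.integer(binWidth),
      values = list(chrT = as.numeric(values)),
      seqinfo = GenomeInfoDb::Seqinfo("chrT", chromLength),
      totalFragments = total, kind = kind)
}
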