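---
title: "m6Akit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6Akit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical
models, what each tunable parameter means and why its default is what it
is, what the synthetic-data generator does and does not emulate, and the
places where the design was genuinely open and a choice had to be made.

# The analysis problem

MeRIP-seq compares an antibody-enriched library (IP) against a matched
unenriched library (input). Methylated fragments are preferentially
retained in the IP, so m6A sites appear as local enrichments of IP
coverage over the input-derived background. At low input the stakes
concentrate in quality control: does the called peak set carry the known
m6A signatures (RRACH consensus, stop-codon proximity), does it
replicate, do spike-in controls behave, and is the significance cutoff
doing real work? `m6Akit` implements the peak caller and this entire
evaluation battery over Bioconductor containers.

# Peak calling

## Model

The candidate unit is the 10-bp bin, consistent with the coverage-track
grid; at fragment lengths near 150 bp a finer unit adds nothing. The test
statistic per bin is the *fragment-overlap pileup*: the number of IP
fragments with at least one exonic block overlapping the bin (each
fragment counts once per bin). The null is Poisson with a local rate
estimated from the input:

$$\lambda_{local} = \max(\lambda_{BG},\ \lambda_d,\ \lambda_{1k},\
\lambda_{5k},\ \lambda_{10k})$$

with $\lambda_w = N_w \cdot K \cdot b / w \cdot r$, where $N_w$ counts
input fragments overlapping the $w$-window centred on the bin, $K$ is the
mean number of bins an input fragment overlaps (measured from the data,
so $\lambda$ lives on the same scale as the pileup), $b$ the bin width
and $r$ the IP/input depth ratio.
$\lambda_{BG} = N_{input} \cdot K \cdot b / G \cdot r$ is the
genome-wide rate over the effective size $G$.

Two modelling points deserve emphasis:

* **The fragment-size window $\lambda_d$ is essential for RNA data.**
  Transcript coverage is concentrated on exons at sub-kilobase scale, so
  kilobase windows systematically underestimate the local rate there;
  without $\lambda_d$ an IP identical to its input yields hundreds of
  spurious "peaks" on well-expressed exons. With it, the null experiment
  is clean, because every fragment contributing pileup at a bin also
  lands in its fragment-size window ($\lambda_d \gtrsim k$ under the
  null).
* **$G$ should be the transcriptome, not the genome.** With a full-genome
  $G$ the background rate is diluted by untranscribed desert, and the
  *depleted* direction (input tested against IP) miscalls every
  expressed exon. `effectiveTranscriptomeSize()` returns the exon-union
  size of the annotation; passing it as `effectiveSize` mirrors the
  common practice of giving RNA peak callers a transcriptome-size
  genome parameter. `G` remains a free parameter because how a
  genome-space Poisson model should interact with a transcriptome-size
  normaliser has no canonical answer.

The window estimator counts fragments overlapping the window, which
overestimates the per-bin rate by roughly $(w + L_f)/w$ (fragments
overlapping the window edge). For kilobase windows this is a ≤15%
conservative bias; for $\lambda_d$ it approaches a factor of two. We keep
the conservative form: it protects the null experiment and the spike-in
false-discovery control, at a small cost in sensitivity that the strong
IP enrichment absorbs.

p-values are Poisson upper tails (`ppois` machinery, stable far into the
tail); q-values are Benjamini–Hochberg over bins with non-zero pileup
only — all-zero bins carry no evidence and would only dilute the FDR
denominator. Significant bins (q < `qCutoff`) merge across gaps ≤
`mergeGap`; merged intervals shorter than `minPeakLength` are dropped.
Each peak reports its minimum-p bin, and its summit is the centre of the
maximum-pileup significant bin, leftmost on ties — one summit per peak,
no sub-peak deconvolution.

## Parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `binWidth` | 10 | bp | coverage-track grid; fragment length ≫ bin |
| `qCutoff` | 0.05 | FDR | standard peak-significance currency |
| `localWindows` | 1000, 5000, 10000 | bp | MACS-style local background scales |
| `mergeGap` | 100 | bp | below one fragment length; joins bins split by sampling noise |
| `minPeakLength` | 150 | bp | about one sonicated fragment |
| `effectiveSize` | NA → data | bp | see above; pass the transcriptome size for RNA data |

Duplicates are collapsed once, before calling (`deduplicate()`, key =
chromosome/start/end/strand); the caller itself never touches duplicates,
so the deduplication policy stays in one place.

# Signal, correlation, PCA

The m6A signal is $\log_2((RPKM_{IP}+1)/(RPKM_{input}+1))$ per 10-bp bin
— finite everywhere, zero where the libraries agree, antisymmetric under
role swap. RPKM is `count / (binWidth/1000 × total/10^6)` with the
fragment-overlap count above. Correlation and PCA aggregate tracks to
1-kb means over *exonic* bins (the union of exons of all annotated
transcripts, materialised at bin resolution — isoform handling needs no
finer definition here). Windows with no exonic bins, or zero value in
every sample, are dropped before correlating; a zero-coverage window has
no defensible value under either convention, and dropping is the
documented choice. PCA centres features, takes the top two singular
directions, and fixes signs so the largest-magnitude loading is positive
— coordinates are then fully deterministic.

`transcriptTPM()` assigns each fragment to the transcript span containing
its genomic midpoint (longest-overlap, then lexicographic id on ties) and
normalises `count/kb` rates to a million. This is deliberately simple —
no isoform-resolution EM — and exact on the simulator's non-overlapping
gene models.

# Motif analysis

The summit's strand is deduced from the transcript under it; where
transcripts on both strands overlap, the higher-TPM transcript wins (ties:
lexicographic id). The 400-bp summit-centred window is scanned for the
RRACH pentamer `[AG][AG]AC[ACT]` on the deduced strand (DNA alphabet;
U↔T is notation only). Enrichment is a binomial upper tail of the peak
fraction against the fraction in random *exonic* 400-bp windows (strand
of the host transcript, reproducible under a seed) — exonic rather than
genome-wide, because peaks live in transcribed sequence and a
genome-wide background would flatter them. This is a targeted stand-in
for de novo motif discovery: the downstream quantity is the RRACH
fraction and its significance, which this reproduces; it is not claimed
equivalent to a discovery tool's background model.

# Annotation and metagene

Feature assignment is priority-ordered — stop codon (±200 bp *genomic*
window, so bases beyond transcript ends still count), 3'UTR, 5'UTR, CDS,
exon, intron, intergenic — and every summit receives exactly one label;
the exon class catches non-coding transcripts (spike-in contigs, retro
loci). A gene is m6A-marked when any feature holds ≥1 summit; the
replicate-supported variant intersects replicates and drops intron from
the qualifying features, matching the two definitions' different feature
lists.

The feature enrichment score is $\log_2(observed/expected)$ with
*expected* proportional to the priority-masked genomic length of each
class (each base counted once, under the same priority order). The
"expected" model is the one genuinely open choice here — shuffled-peak
nulls are an alternative — and length-proportionality is the documented
one: it is deterministic, and consistent with the assignment rule.
Features with zero observed peaks report `-Inf`.

Metagene profiles map each summit to its host gene's top-TPM isoform
(ties: longer transcript, then id), position it fractionally within
5'UTR/CDS/3'UTR, and rescale the segments to unit length: \[0,1) 5'UTR,
\[1,2) CDS, \[2,3\] 3'UTR, with the stop codon at exactly 2.0. The
density is a 30-bins-per-segment histogram normalised to unit area;
summits outside the selected isoform's exons are dropped and counted.

# Reproducibility battery

Overlap between peak sets is ≥1-bp interval intersection (asymmetric:
fraction of *query* peaks), with summit-in-peak as an option. The q-value
sweep calls peaks once at the loosest cutoff and filters that single call
at each stricter cutoff — one BH pass, no re-ranking — so counts are
monotone by construction and the interesting question is whether the
*quality* metrics (RRACH fraction, stop/3'UTR fraction, replication)
move. Downsampling draws without replacement per seed and re-calls with
identical configuration; the input-vs-itself control should stay at ~0
peaks at every depth. Spike-in false discovery is simply the peak count
on the modified vs the unmodified contig.

# qPCR

The Ct model is $Ct = intercept - \log_2(conc) + \mathcal N(0, sd)$ with
perfect per-cycle doubling (efficiency is fixed at 2, as the S/N formula
assumes; it is deliberately not a parameter). Zero concentration is
censored (`NA`), never imputed to a pseudo-cycle, and censored values
propagate as errors in downstream formulas. Input Cts are corrected by
$-\log_2(1/f)$ for input fraction $f$; the S/N ratio is
$2^{\Delta Ct_{pos}} / 2^{\Delta Ct_{neg}}$; titration recovery
normalises IP Cts to the 100% mix ($100 \cdot 2^{Ct_{norm} - Ct_i}$, 0%
for censored mixes).

# The synthetic-data generator

## What it emulates

One integer seed drives named substreams (annotation / sites /
expression / each library / qPCR / backgrounds), so every stage is
independently reproducible and the whole pipeline is byte-identical
across runs. The standard study (the `simConfig()` defaults) is:

* ~3 Mb across 4 chromosomes; 300 spliced protein-coding gene models
  (1–3 exons, introns 200–800 bp) on both strands with 5'UTR 100–300,
  CDS 300–1500 (codon-rounded), 3'UTR 250–800 bp; log-normal expression
  (meanlog 1, sdlog 1).
* 200 m6A sites per condition, planted on genuine RRACH adenosines in
  exonic sequence; a site is stop-codon-proximal (within 400 bp) with
  probability 0.7, and proximal candidates are drawn with weight
  $e^{-d/100\,bp}$ so the site density is sharply centred on the stop
  codon, as the assay's metagene profiles show. Stoichiometry is uniform
  on \[0.5, 1\]. Sites of one condition keep ≥600 bp spacing so enriched
  regions (± one fragment length) stay resolvable at the caller's summit
  precision; conditions draw disjoint site sets.
* Libraries of 2×10^5 fragments; length ~ N(150, 30) truncated at 30 bp,
  start uniform along the transcript, coordinates projected through exon
  blocks (spliced fragments carry BED12-style split blocks). IP
  selection is per-fragment Bernoulli — weight `stoichiometry × 8` when
  the fragment covers a planted site, `0.05` otherwise — then truncation
  to the fixed library size, mirroring equimolar pooling.
* Two 550-bp spike-in contigs carried through the pipeline like
  chromosomes: GLuc-like fully modified (every RRACH marked,
  stoichiometry 1), CLuc-like unmodified.
* Two retrotransposon subfamilies, 20 loci each at 92–100% of consensus
  length, placed intergenic: MTA-like (methylated, ≤2 sites per locus)
  and L1-like (unmethylated).
* qPCR Ct via the model above (intercept 30, sd 0.2 by default).

Two generator choices are worth flagging because they are *not* neutral:

* **Base composition is pyrimidine-rich** (A = G = 0.12, C = T = 0.38).
  Under a uniform composition the RRACH pentamer occurs about once per
  170 bp and essentially every 400-bp window contains one, so
  window-level motif statistics would be uninformative. The chosen
  composition puts the background rate near one per kilobase, keeping
  the peak-vs-background contrast meaningful. Real transcriptomes sit in
  between; the absolute background fraction is therefore a property of
  the toy genome, not a prediction.
* **Guaranteed motif instances** are written into the sequence (one
  stop-proximal RRACH per gene, three per spike-in, two per retro locus)
  so the site planter never starves regardless of the random sequence.

## What it does not emulate

Sequencing error, base qualities, multi-mapping reads, rRNA
contamination, GC or length biases, isoform diversity (one transcript
per gene), overlapping genes, nested repeats, antibody batch effects,
and PCR-duplicate structure (duplicates arise only by chance collisions).
Passing tests therefore demonstrate the *statistical logic* of the
pipeline — recovery of planted enrichment under Poisson-like sampling,
correct normalisation and bookkeeping — not robustness to the technical
artefacts of real libraries.

## Scale of the shipped analyses

The package's tests and the acceptance script run the standard study
(300 genes, 2×10^5 fragments per library, two replicates; a two-condition
variant for PCA) and smaller structured fixtures for unit-level checks.
These sizes give stable statistics for every claim the package makes
while keeping a full run in minutes on a single core.

# Degenerate inputs and numerical conventions

Empty fragment sets produce empty (all-zero) tracks and empty peak sets
with a warning; an input with zero fragments makes the caller fall back
to an IP-derived uniform background, flagged in a warning. Zero-variance
tracks yield `NA` correlations. Binomial/Poisson tails are computed by
the stats machinery in log space. TPM sums to 10^6 to within 1e-6
relative whenever any fragment is assigned. Metagene densities integrate
to 1 within 1e-9. Ties are broken deterministically everywhere
(lexicographic ids, leftmost bins), and every random draw flows from a
named substream of one seed.

# Known limitations

* One summit per peak; closely spaced sites (< ~300 bp) merge and only
  the dominant one is localised.
* The window-count background estimator is conservative at the
  fragment-size scale (see above).
* Proportional mapping of retro loci onto their consensus is an affine
  approximation to alignment-based coordinates; fine positional features
  within a subfamily should not be over-read.
* `fraction methylated` uses the replicate-*mean* signal per locus
  (> 0 threshold taken literally); a per-replicate intersection variant
  would be stricter.
* The binomial motif-enrichment test conditions on a fixed background
  fraction estimated from sampled windows; its p-values are meaningful
  for ranking and thresholding, not as calibrated genome-wide FDRs.
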