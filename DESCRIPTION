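Package: m6Akit
Title: Simulation and Downstream Analysis of Low-Input m6A MeRIP-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of methylated-RNA
    immunoprecipitation sequencing (MeRIP-seq) at low input, from aligned
    IP/input fragments to m6A peaks and summary statistics. Includes a
    model-based Poisson peak caller with MACS-style local background and
    Benjamini-Hochberg q-values, binned RPKM coverage and log2 IP/input m6A
    signal tracks, transcript TPM estimation, RRACH motif scanning and
    enrichment testing, priority-ordered peak annotation with metagene
    profiles, replicate-overlap, downsampling-saturation and q-value-sweep
    reproducibility analyses, retrotransposon subfamily methylation
    quantification, and qPCR signal-to-noise and titration-recovery
    statistics. A fully parameterised synthetic-data generator produces toy
    genomes, planted m6A sites at RRACH motifs with stop-codon bias,
    IP-enriched fragment libraries, modified/unmodified spike-in contigs and
    Ct tables, so every stage is testable against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'coverage.R'
    'io.R'
    'm6Akit-package.R'
    'motif.R'
    'peaks.R'
    'qpcr.R'
    'reproducibility.R'
    'retro.R'
    'simConfig.R'
    'simulate-fragments.R'
    'simulate-genome.R'
    'simulate-sites.R'
    'tpm.R'
    'utils.R'
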