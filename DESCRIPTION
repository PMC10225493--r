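Package: dioscan
Title: Sex-Linked Region Discovery, Sweep Scans, LTR Dating and Karyotype
    Fusion Analysis for Dioecious Plant Genomes
Version: 0.1.0
Authors@R:
    person("dioscan", "developers", email = "dioscan@example.org",
           role = c("aut", "cre"))
Description: Tools for small dioecious plant genomes with XY-type sex
    determination. Discovers male- and female-specific k-mers from sexed
    resequencing cohorts by prefix-subsampled k-mer cataloguing, labels
    sex-specific reads and localizes the sex-determining region (SDR) from
    windowed depth tracks; scans wild versus domesticated SNP panels for
    selective sweeps with windowed Weir-Cockerham FST, nucleotide diversity
    (pi), pi ln-ratio and Tajima's D; dates long terminal repeat (LTR)
    retrotransposon insertions from 5'/3' LTR divergence via the Kimura
    two-parameter distance and T = K/(2r); and analyses karyotype evolution
    by detecting evolutionary fusion regions (EFRs) between homologous
    synteny blocks and counting fusion/fission events against an ancestral
    karyotype. Every analysis is paired with a synthetic-data generator
    that emits the corresponding inputs with machine-readable ground truth,
    so the whole pipeline can be exercised end-to-end at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    Rsamtools,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
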