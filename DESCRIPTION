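Package: maccr
Title: Chromatin Accessibility from MNase Titration Series (MACC)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes MNase accessibility (MACC) scores from paired-end
    micrococcal nuclease titration data: per-bin linear-regression slopes of
    normalized fragment frequency against log MNase concentration, with
    significance weighting, LOWESS GC-bias correction (optionally stratified
    by CpG-island membership) and median shifting. Downstream analyses
    include two-state Gaussian hidden-Markov segmentation of the genome into
    accessible and inaccessible states, strict local-maximum peak calling,
    classification of bins into non-histone-protection (group 1) and
    accessible-nucleosome (group 2) sets from chromatin versus histone-ChIP
    scores, randomized peak-site overlap estimation, annotated-region
    enrichment, site-centered average profiles and UPGMA clustering of
    per-sample profiles. A synthetic titration simulator with known per-bin
    ground truth supports end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    yaml,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
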