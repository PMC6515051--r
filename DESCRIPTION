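Package: wgdks
Title: Detection and Dating of Whole-Genome Duplications from Ks Age
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds paralog gene families from coding sequences by exact
    protein local alignment with Karlin-Altschul E-value statistics,
    estimates pairwise synonymous divergence (Ks) both by Nei-Gojobori
    (1986) counting and by maximum likelihood under a Goldman-Yang codon
    model with F3x4 frequencies, corrects the redundancy of large families
    by duplication-node weighting, fits Gaussian mixture models to
    log-transformed Ks age distributions with BIC model selection, and
    converts Ks peaks into absolute ages (or substitution rates) with the
    molecular-clock formula T = Ks / (2 r).  A codon-level simulator
    generates transcriptome-like paralog populations with known
    duplication histories (exponential small-scale-duplication background
    plus log-normal whole-genome-duplication bursts) so that the entire
    pipeline can be validated end to end.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    data.table,
    graphics,
    grDevices,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
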