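Package: codonsel
Title: Codon Models of Positive Selection and Selection Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood codon substitution models for detecting positive
    selection and selection divergence in protein-coding genes, in the style of
    PAML/codeml analyses of mammalian gene families. Implements Goldman-Yang rate
    matrices, Felsenstein pruning over site-class mixtures (M0, free-ratio,
    branch-site model A, M2a_rel, Clade Model C), likelihood-ratio tests,
    empirical-Bayes identification of selected or divergent sites, marginal
    ancestral codon reconstruction, protein-guided back-translation of coding
    sequences into codon alignments, a codon alignment simulator with recorded
    truth, and the additive five-sites spectral-tuning predictor for
    long-wavelength opsins.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
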