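Package: rnaquant
Title: Transcript and Gene Abundance Estimation for RNA-Seq by
    Expectation-Maximization and Gibbs Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies isoform- and gene-level abundances from single-end or
    paired-end RNA-Seq reads aligned to a set of reference transcript
    sequences. Reads are modelled with a generative model covering fragment
    and read length distributions, a read start position distribution,
    quality-score or position-dependent sequencing error models, and a noise
    component for unalignable reads. Maximum-likelihood abundances are
    computed by expectation-maximization with a repeat/poly(A) filter bias
    correction; posterior mean estimates and credibility intervals are
    obtained by two-stage collapsed Gibbs sampling. The same model drives a
    read simulator with ground truth, enabling closed-loop validation, and
    helpers compute standard accuracy statistics (median percent error,
    error fraction, false positive rate), credibility-interval coverage and
    transcript mappability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
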