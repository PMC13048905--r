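Package: rootsignal
Title: Dissecting Conflicting Root-Placement Signals in Phylogenomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and dissecting conflicting root-placement
    signals in phylogenomic amino-acid datasets. Implements a per-gene signal
    census with chi-squared tests, single-signal concatenations, site
    jackknifing with pooled-bootstrap consensus support, site-heterogeneous
    profile-mixture and posterior-mean site-frequency (PMSF) likelihood
    analyses, parametric-bootstrap model-adequacy tests (amino-acid diversity
    and maximum compositional deviation Z-scores), per-taxon compositional
    chi-squared diagnostics with Dayhoff-6 recoding, gene and site concordance
    factors, approximately unbiased (AU) topology tests via multiscale RELL
    resampling, and a synthetic multi-signal data generator for calibrating
    the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
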