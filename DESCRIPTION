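Package: clonesect
Title: Clonal Decomposition of Multi-Section Tumor Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the clonal composition of a tumor from variant and total
    read counts measured across multiple physical subsections plus a matched
    normal. A binomial generative model over allele counts is fitted by a
    customized expectation-maximization algorithm, yielding binary clone
    genotypes, per-subsection clone frequencies, and a BIC-based choice of the
    number of clones. Includes a perfect-phylogeny consistency analysis with
    one-bit "nearby" genotype repair and likelihood rescoring, a simulator for
    multi-section deep-sequencing counts with optional read-flip noise,
    permutation-matched genotype and frequency error metrics, and a
    Fisher-exact multi-sample somatic variant screen on allele-count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
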