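Package: slimdiv
Title: Divergence of Short Linear Motifs after Gene Duplication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects type I functional divergence (lineage-specific changes in
    evolutionary constraint) in short linear motifs after gene duplication.
    Implements a clade-rate likelihood-ratio test under local molecular
    clocks whose null distribution is calibrated by a data-dependent
    non-central chi-squared via Kullback-Leibler divergence estimated from
    whole-protein evolution, a phylo-HMM predictor of conserved segments in
    disordered regions, a modified Storey false-discovery-rate procedure
    robust to a point mass of uninformative tests, a permutation test for
    lineage bias in paralog pairs, and an amino-acid sequence evolution
    simulator with indels, ordered/disordered substitution regimes and
    clade-specific rate shifts used to validate the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
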