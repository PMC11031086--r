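Package: coreceptR
Title: Evolutionary and Proximal-Signaling Analysis of T-Cell Coreceptor Motifs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying the functional importance of conserved motifs in
    the CD4 coreceptor and for analysing the bespoke cell-biology assays used to
    probe them. Covers per-residue evolutionary analysis of ortholog alignments
    (entropy-based conservation scores normalized to mean 0 / SD 1, mutual
    information covariation with average-product correction and a dual-threshold
    calling rule, per-site dN/dS likelihood-ratio tests under an MG94-style
    codon model, and marginal ancestral sequence reconstruction on a fixed
    tree), paired-stimulation flow-cytometry histogram differencing (percent
    responders, background-subtracted mean intensity and SEM, nearest-neighbour
    smoothing), sucrose-gradient FFLISA normalization with DRM/DSM area-under-
    curve analysis, IL-2 dose-response summaries, and percent-of-control summary
    tables. A seeded synthetic-data module generates every input with known
    ground truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
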