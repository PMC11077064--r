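Package: comphom
Title: Compositional Homology Analysis of Intrinsically Disordered Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies compositional homology between protein sequences with a
    normalized chi-square test of homogeneity (chi-score), detects
    compositionally distinct modules within a single sequence by permutation
    z-score validated boundary segmentation, contrasts compositional
    similarity with global-alignment linear sequence similarity against
    scrambled-self null baselines, profiles intrinsically disordered regions
    (net charge per residue, fraction of charged residues, isoelectric point,
    CDK phosphorylation consensus motifs, AT-hooks, phospho-site window
    matrices), and computes chromosome/cytosol partitioning metrics from
    live-imaging ROI statistics tables. Includes seeded synthetic-sequence and
    synthetic-ROI generators so every analysis stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
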