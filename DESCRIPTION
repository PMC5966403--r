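Package: SpliceScreen
Title: Screening, Splicing and Stem-Loop Ensemble Analytics for
    RNA-Structure-Targeted Drug Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for target-based discovery of small molecules
    that bind an RNA stem-loop and modulate alternative splicing.
    Implements fluorescence-displacement plate analytics (Z-factor
    quality control, per-replicate displacement activity, Welch tests
    with Bonferroni-controlled hit calling, autofluorescence flagging,
    four-parameter logistic EC50 fits), exon-inclusion quantification
    (percent inclusion from band intensities, percent of maximum
    inclusion increment, 2^-ddCt fold changes, structural-probe deltas
    and their correlation with splicing, circular-dichroism extrema),
    junction-count differential splicing (percent-spliced-in and
    delta-PSI filters, an on-target versus off-target response
    classifier, splice-donor motif enrichment), and geometry analytics
    over multi-model stem-loop coordinate ensembles (Kabsch
    superposition, pairwise bundle RMSD, RMSF, distance observables,
    loop-state classification).  Seeded synthetic-data generators
    emulate every input so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
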