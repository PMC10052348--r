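Package: pcmscreen
Title: Proteochemometric Modeling and Virtual Screening for Transporter Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteochemometric (PCM) virtual-screening pipeline for
    transporter ligand discovery. Curates bioactivity tables into
    deduplicated pChEMBL datasets, computes compound (ECFP, physicochemical)
    and protein (Z-scale autocross-correlation, composition) descriptor
    blocks, selects related training targets from sequence-similarity
    networks and phylogenetic layers scored by cross-validated random
    forests, trains stacked ensembles (random forest and gradient boosting
    bases under a partial-least-squares meta-learner), screens compound
    libraries with affinity and similarity-band novelty filters followed by
    density-based clustering of hits, and analyses impedance-based transport
    assay traces into normalized responses and pIC50 values. Synthetic-data
    generators with known ground truth make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    ape,
    igraph,
    ranger,
    xgboost,
    mixOmics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: OpenBabel (>= 3.0, the obabel executable)
Config/testthat/edition: 3
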