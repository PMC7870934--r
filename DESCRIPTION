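Package: tcmimmuno
Title: Systems Pharmacology Screening of Herbal Natural Products for
    Cancer Immunotherapy
Version: 0.1.0
Authors@R:
    person("TCM", "Screen Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A quantitative network-pharmacology toolkit for prioritising
    herb-derived natural products as cancer-immunotherapy candidates.
    Screens herbs against a disease by hypergeometric literature
    co-occurrence with Benjamini-Hochberg control, assembles tripartite
    herb-compound-target networks with direct/indirect edge
    classification at a 10 micromolar binding-affinity threshold,
    integrates curated cancer immune response (CIR) gene sets, scores
    each compound's target set against permutation nulls drawn from the
    protein-coding genome (with an exact hypergeometric fast path),
    combines five gene-set models into a consensus Z ranking, and
    clusters predicted positives by Tanimoto distance over circular
    feature-class fingerprints using k-medoids. Ships a seeded
    synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python with RDKit (optional; only for computing
    fingerprints from SMILES)
Config/testthat/edition: 3
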