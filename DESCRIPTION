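Package: hubnet
Title: Multi-Omics Pathway-Network Meta-Analysis with Hub-Molecule Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous omics datasets (quantitative
    transcriptomics and proteomics, presence-only protein, nitroprotein and
    phosphoprotein inventories) against a user-supplied knowledge base of
    molecular interactions (SIF) and canonical pathway gene sets (GMT).
    Performs per-dataset pathway over-representation analysis (one-sided
    hypergeometric test with Benjamini-Hochberg correction), constructs
    bounded, scored molecular subnetworks by deterministic seed-and-extend
    greedy growth, extracts hub molecules by induced degree, ranks hubs by
    cross-dataset frequency, cross-tabulates high-frequency hubs against
    immunoaffinity phosphopeptide quantification with a signed fold-change
    convention, and applies target-decoy false discovery rate thresholds to
    peptide-spectrum matches. Includes a fully seeded synthetic-data
    generator with planted hubs, planted enriched pathways and planted
    phosphopeptide ratios for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
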