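Package: orthoid
Title: Dual-Orthogonal Proximity-Labeling Proteomics Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained analysis pipeline for dual-orthogonal
    proximity-labeling proteomics (OrthoID). Two enzymes label residues on
    opposite faces of the ER-mitochondria interface: biotin (Bt, +226.078 Da)
    on cytosol-exposed lysines and an adamantane-phenol tag (Ad, +414.252 Da)
    on ER-lumen-exposed tyrosines. The package simulates topology-annotated
    proteomes and labeled MS/MS spectra with full ground truth, identifies
    mass-shifted peptides with a modification-aware search engine under
    reverse-decoy FDR control, and classifies mitochondria-associated
    ER-membrane (MAM) candidate proteins by replicate consensus, annotation
    filtering, arm intersection, topology validation, and condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
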