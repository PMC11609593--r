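Package: fodm
Title: Fuzzy Oil Drop Assessment of Protein Hydrophobic Cores and Domain
    Swapping
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative assessment of protein structural units with the
    fuzzy oil drop model and its environment-modified extension. Reduces
    residues to effective atoms, spans a 3D Gaussian envelope over a
    structural unit to obtain the theoretical hydrophobicity distribution,
    computes the observed distribution from distance-weighted pairwise
    hydrophobic interactions, and compares the two through Kullback-Leibler
    divergence (the RD statistic) and a fitted environment parameter K.
    Structural units may be composed of fragments of several chains, which
    makes the with/without-guest analyses used in domain-swapping studies
    reproducible from PDB or mmCIF coordinates. Includes synthetic
    effective-atom generators with controlled statistics for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'scale.R'
    'selection.R'
    'structure-io.R'
    'envelope.R'
    'observed.R'
    'divergence.R'
    'modified.R'
    'status.R'
    'swap.R'
    'synthetic.R'
    'plot.R'
    'fodm-package.R'
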