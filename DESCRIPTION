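Package: prodomainCys
Title: Conserved Prodomain Cysteines and Common-Phenotype Interaction
    Inference in the Human TGF-beta Family
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects conserved cysteines in aligned TGF-beta family
    prodomains using BoxShade-style similarity shading, assigns positional
    Cys@ labels inside the Association and beta-8 region windows,
    intersects conserved positions with cysteine-affecting disease
    mutations, and applies the common-mutant-phenotype rule to propose
    heterodimer pairs and partner-protein binding interactions.  Also
    compares cysteine spacings and acidic docking-site residues across
    TGF-beta-binding (8-Cys) and EGF-like domains of the LTBP and
    fibrillin partner proteins, and ships a synthetic family generator
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: SequenceMatching, Alignment, Proteomics, VariantAnnotation
RoxygenNote: 7.3.3
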