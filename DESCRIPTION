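Package: decomplexR
Title: Decomplexing Venomics Quantification and Antivenom Immunoprofiling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for decomplexing (fraction-resolved, bottom-up) snake
    venomics. Converts an RP-HPLC chromatogram and per-fraction
    peptide-spectrum match (PSM) tables into whole-venom protein-family
    compositions: baseline correction and trapezoidal integration of
    fraction shares, score/SPI filter cascades with target-decoy FDR
    control, mean-spectral-intensity (MSI) quantification within
    fractions, hierarchical whole-venom abundance estimation, toxin-family
    aggregation, non-redundant protein counting and two-venom comparison.
    Also summarises indirect ELISA immunoprofiles of antivenoms against
    chromatographic fractions, ships a curated reference dataset of two
    Daboia siamensis venom proteomes, and includes a fully seeded
    synthetic-experiment generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software
RoxygenNote: 7.3.3
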