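Package: hipquant
Title: Quantitative Immunopeptidomics with Internal pMHC Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Internal-standard normalization and absolute quantification for
    mass-spectrometry immunopeptidomics. Reads peptide-spectrum-match (PSM)
    tables from label-free or isobarically labeled (TMT) experiments, applies
    the post-search filters used for MHC class I peptides, derives per-sample
    or per-channel correction factors from heavy-isotope-coded peptide-MHC
    (hipMHC) standards spiked into lysate, estimates dynamic-range suppression
    from titrated standards, converts embedded calibration curves of
    chromatographic apex intensities into copies per cell, and computes
    fold-change, mean-adjusted significance and pre-ranked gene-set enrichment
    statistics. A seeded simulator generates PSM tables and targeted runs with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse
Config/testthat/edition: 3
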