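Package: ire1cld
Title: Quantitative Analysis of Unfolded-Protein Sensing by the IRE1alpha
    Core Lumenal Domain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for studying how the core lumenal domain
    (cLD) of the endoplasmic-reticulum stress sensor IRE1alpha recognizes
    unfolded proteins and oligomerizes.  Implements per-amino-acid
    enrichment statistics for peptide tiling arrays, Hill-type log-dose
    binding-isotherm fitting for fluorescence-anisotropy and
    thermophoresis titrations, methyl-TROSY chemical-shift-perturbation
    classification and paramagnetic-relaxation-enhancement (PRE)
    broadening profiles normalized by Shrake-Rupley solvent accessibility,
    and Calpha-Calpha cross-link distance-restraint analysis for
    nominating oligomerization interfaces.  A synthetic-data layer
    generates every input with known ground truth so the full pipeline is
    testable end to end, and numbered driver scripts under analysis/
    reproduce the workflow.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    seqinr,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
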