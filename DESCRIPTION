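Package: neomyelin
Title: Synthetic Quantitative MRI and Myelination Scoring for the Neonatal Brain
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multi-dynamic multi-echo (MDME) quantitative MRI
    study of brain myelination in preterm and term-born neonates. Provides
    digital neonatal-brain phantoms with a maturational (gestational-age
    dependent) T1/T2 relaxation model, forward simulation and voxelwise
    fitting of the MDME saturation-recovery multi-echo acquisition,
    retrospective synthesis of conventional T1-/T2-weighted contrasts from
    quantitative maps, the seven-region Myelin Total Score (0-28) with
    relaxation-constant criteria, simulated raters, and the cohort
    statistics layer (inclusion filtering, preterm/term allocation,
    two-rater intraclass correlation, Pearson correlation with
    gestational age at MRI, and ANCOVA group comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
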