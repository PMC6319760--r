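Package: qstab
Title: Fraction-of-Native-Contacts Stability Analysis for Single-Domain Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of molecular-dynamics trajectory ensembles to
    estimate the relative thermal stability of single-domain antibodies
    (VHH/sdAb) and other small protein domains. Computes the soft
    (logistic-weighted) fraction of native contacts Q against a reference
    crystal structure, decomposes Q by physicochemical residue groups
    (hydrophilic, hydrophobic, small) and per residue, detects unstable
    residues from final-window averages, correlates per-system Q with
    experimental melting temperatures, and compares engineered variants
    against a wild type. Includes a deterministic synthetic-trajectory
    generator with designed per-residue instability so the whole pipeline
    can be exercised and validated without running molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
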