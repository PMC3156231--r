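Package: nrpred
Title: Two-Level Nuclear Receptor Subfamily Prediction from Sequence-Derived
    Pseudo Amino Acid Composition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies nuclear receptors (NRs) and their subfamilies from
    protein sequence alone. Sequences are encoded as an 881-dimension weighted
    pseudo amino acid composition vector built from four descriptor families
    (amino acid composition, gapped dipeptide compositions, Lempel-Ziv
    complexity, and low-frequency Fourier spectrum components of
    physicochemical property signals) and classified with a fuzzy K-nearest
    neighbor rule in a two-level cascade: NR versus non-NR, then one of seven
    NR subfamilies. Includes jackknife cross-validation with per-class
    accuracy and Matthews correlation coefficients, a 2-D (K, m) grid search,
    feature-ablation reports, and a seeded synthetic protein-family generator
    so the full pipeline is testable without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
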