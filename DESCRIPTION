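Package: krillipids
Title: Identification, Quantification and Composition Analysis of Intact
    Phospholipids from Dual-Polarity LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based annotation of diacyl glycerophospholipids from
    dual-polarity high-resolution LC-MS/MS feature tables, built around
    exact monoisotopic mass arithmetic for head-group fragment ions and
    neutral losses. Confirmed species are quantified against class-matched
    internal-standard calibration curves with iterative Grubbs outlier
    screening, and per-sample percentage compositions feed seasonal
    comparison statistics: molecular-weight/unsaturation grouping, PCA,
    between-season abundance ratios, SFA/MUFA/PUFA ternary compositions
    and EPA/DHA indices. A deterministic simulator generates krill-like
    lipidomes rendered to noisy peak lists in both ionization modes so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
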