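Package: proteoid
Title: Reidentification Analysis for Longitudinal Plasma Proteomes
Version: 0.1.0
Authors@R:
    person("Proteoid", "Developers", email = "proteoid@example.org", role = c("aut", "cre"))
Description: Tools to quantify how identifiable individuals are from
    longitudinal blood plasma proteome profiles. Selects individual-specific
    proteins (stable within a person, divergent between people), reassigns
    blinded samples to donors by Pearson correlation of those proteins,
    builds a panel of allele-discriminating variant (SAAV) peptides via
    in-silico tryptic digestion and a multi-stage evidence filter cascade,
    matches samples by present/absent variant-peptide calls, and screens for
    incidental marker spikes. Includes a seeded synthetic-cohort generator
    emulating the variance structure and data-dependent-acquisition dropout
    of real plasma profiling studies, so the whole pipeline is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
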