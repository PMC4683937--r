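Package: gracepcr
Title: Copy-Number Genotyping of the Alpha-Globin Genes from Multiplex Melt Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene ratio assay copy enumeration PCR (GRACE-PCR) data
    analysis: determine HBA1 and HBA2 copy numbers relative to a two-copy
    CLCN7 reference amplicon from multiplex high-resolution melting curves.
    Implements two independent calling procedures (negative-derivative peak
    height ratios normalized to a wild-type control, and two-stage
    normalization-window plateau ratios), interprets copy-number pairs as
    alpha-thalassaemia genotype classes, and validates performance against a
    truth table with exact binomial (Clopper-Pearson) confidence intervals.
    Includes a seeded melt-curve simulator whose per-amplicon melt transitions
    have amplitudes proportional to gene copy number, for fixtures and
    cohort-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    optparse,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
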