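Package: exoflux
Title: Exo-Metabolome Footprinting of Bacterial Transporter Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for untargeted LC-MS exo-metabolome
    (metabolic footprint) time courses of bacteria incubated in human
    serum. Provides a ground-truth simulator of the serum-incubation
    design (wild type plus paired transporter knockout/overexpression
    strains, serum-only controls, pooled QC injections with instrument
    drift), QC-based LOESS signal correction and QC-CV filtering,
    feature deduplication by exact mass and retention time,
    identification-confidence levels from spectral-library evidence,
    import/export calling from linear/exponential fits and fold-change
    rules, differential-transport selection of mutant versus wild type,
    and knockout/overexpression convergence logic that infers candidate
    transporter substrates and their transport direction.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
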