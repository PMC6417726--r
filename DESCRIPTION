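Package: beecuticle
Title: Comparative Analysis of Adult Cuticle Maturation in Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting heterochronic shifts in adult cuticle
    maturation across bee species from integument transcriptomes, cuticular
    hydrocarbon (CHC) profiles and cuticle-thickness measurements. Provides
    seeded synthetic-data generators emulating a three-species (two eusocial,
    one solitary) by three developmental-phase (pharate adult, newly emerged,
    forager) design; negative-binomial differential-expression calling with
    upregulation-proportion z tests; hierarchical clustering with multiscale
    bootstrap AU/BP support; cross-species ortholog expression-profile
    correlation classification; thresholded co-expression networks and their
    cross-species intersection; internal-standard GC-MS calibration with
    relative and absolute CHC quantification; and a decision-tree comparison
    of cuticle thickness across phases (ANOVA/Tukey, Kruskal-Wallis/
    Conover-Iman, Student's t) with compact-letter displays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
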