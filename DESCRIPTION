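Package: redoxroot
Title: Ratiometric roGFP2 Redox Imaging, DNA-Content Cell-Cycle Gating, and
    Root Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A simulation-backed analysis pipeline for quantifying
    subcellular glutathione redox state in plant root meristems from
    two-channel (405/488 nm excitation) roGFP2 fluorescence images:
    probe calibration from fully reduced and fully oxidised reference
    sets, background-subtracted region-of-interest ratiometry, degree of
    oxidation, and Nernst redox potentials.  Companion modules estimate
    G1/S/G2 cell-cycle phase fractions from DNA-content flow-cytometry
    event tables, compute root growth rates and treatment recovery, and
    compare groups with one-way ANOVA plus Tukey HSD and compact letter
    displays.  A synthetic-data generator with known ground truth
    (images, flow events, root-length tables) makes every stage of the
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
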