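Package: mirtail
Title: Quantification of miRNA 3' Mono-Adenylation from Small RNA-Seq and
    qPCR Rescue Screens
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify 3' non-templated mono-adenylation of mature
    miRNAs from small RNA-seq libraries by exact counting against paired
    canonical and "+A" references, to filter and score per-miRNA adenylation
    levels with one-way ANOVA and Fisher's LSD post hoc tests, to run
    U6-normalized 2^-ddCt miRNome screens for miRNAs that are downregulated
    in disease and restored upon knockdown of a candidate driver, and to
    apply standard plate-assay formulas (LDH relative cell death,
    dual-luciferase ratios, control-mean normalization). Includes a
    ground-truth simulator for reads, Ct panels, and assay plates so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
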