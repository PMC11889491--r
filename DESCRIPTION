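Package: sexome
Title: Paired Before/After Genital Microbiome Transfer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for couple-paired before/after intercourse 16S
    rRNA amplicon sequence variant (ASV) tables: prevalence-based contaminant
    identification against negative controls, low-abundance filtering, alpha
    and beta diversity (Shannon, Bray-Curtis, principal coordinates analysis,
    one-factor PERMANOVA), vaginal community state type assignment, and
    directional bacterial-transfer classification between sexual partners
    (baseline communities, cohort-unique ASVs, transferred and introduced
    taxa, contributor genera). Includes a synthetic-cohort simulator with
    planted transfer events, contaminants, controls and a mock community for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    Biostrings,
    optparse,
    withr
Config/testthat/edition: 3
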