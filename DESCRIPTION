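Package: quartetvar
Title: Pedigree-Aware Variant Prioritization for Family Quartets with an
    Ungenotyped Parent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-stage prioritization of exome variants in a family quartet
    (two affected brothers, unaffected father and sister, ungenotyped mother):
    shared-in-affected, recessive and X-linked hemizygous genotype filters,
    compound-heterozygote detection with a missing parent, consequence-class
    and population allele-frequency filters, gene-panel and erythroid
    expression-library intersection, hypergeometric pathway over-representation
    with Benjamini-Hochberg adjustment, and an ACMG-style evidence combiner
    (PM1/PM2/PM4). Also implements the deterministic arithmetic of erythrocyte
    pyrimidine 5'-nucleotidase functional assays: inorganic-phosphate
    calibration, hemoglobin quantification by Beer-Lambert at 512 nm, specific
    enzymatic activity with zero-time controls, fold change,
    purine/pyrimidine ratio, eosin-5-maleimide percent-of-reference, and
    dual-luciferase normalization. A seeded synthetic quartet-exome generator
    produces VCF, PED, gene-set, pathway and assay-plate inputs with known
    ground truth for end-to-end recovery tests.
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
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
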