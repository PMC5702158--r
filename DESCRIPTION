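Package: dosesig
Title: Gene-Tissue Expression Signatures for Warfarin Dose from Cis-Regulated Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Imputes tissue-specific, genetically regulated gene expression from
    cis-SNP dosages using sparse (LASSO) linear models trained on a reference
    panel, either per-cohort (restricted to the SNPs a cohort actually measured)
    or from a pre-trained weights database. Learns stable gene-tissue signatures
    that explain the residual of the IWPC pharmacogenetic warfarin dosing
    algorithm via repeated cross-validated LASSO with strict-majority stability
    selection, and evaluates them against shuffled-dose and random-signature
    empirical null models with FDR control. Includes a synthetic-data module
    that emulates a reference expression panel and genotyped patient cohorts
    with planted dose effects, so every stage of the pipeline is testable
    end to end without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
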