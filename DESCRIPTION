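Package: muscalink
Title: Autosome-Level Linkage and Co-Regulation Analysis of Up-Regulated
    Genes in House Fly Substitution Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers autosome-level co-regulation of up-regulated
    insecticide-resistance genes from a five-line autosome-substitution
    design in the house fly (Musca domestica). Provides 2^-ddCt qPCR
    quantification with Welch's t-test significance calling, linkage-set
    calling across substitution lines, exact-subset (Venn) partitioning of
    co-regulation classes, allele-specific PCR physical mapping, cis/trans
    regulatory classification, a simplified negative-binomial
    differential-expression screen with BH FDR control, and a synthetic-data
    generator that emulates the genetic design so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
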