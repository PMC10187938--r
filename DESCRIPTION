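Package: epideviate
Title: Somatic and Transgenerational Methylation Deviations in F2 Intercrosses
Version: 0.1.0
Authors@R:
    person("Methylome", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for gene-body CG methylation inheritance in a
    two-parent F2 intercross design. Calls binary methylation states from
    bisulfite read counts, infers local ancestry from low-coverage marker data
    with a three-state hidden Markov model, reconstructs F1 per-allele
    epigenotypes from F2 segregation, quantifies somatic gains and losses of
    methylation as mappable quantitative phenotypes, tests independence of
    deviations between individuals against a binomial null model, maps
    trans-acting QTL on windowed deviation phenotypes by Haley-Knott regression
    with genotype-by-environment interaction, partitions phenotypic variance,
    and estimates transgenerational epimutation rates from grandparent-to-F1
    comparisons. Includes a forward simulator of the full study design used for
    parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
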