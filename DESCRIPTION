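Package: sclc
Title: Multiple-Phenotype Association Tests from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Joint association tests between a genetic variant and many
    correlated phenotypes using only genome-wide association study (GWAS)
    summary statistics. Implements the summary-statistic clustering linear
    combination test (sCLC): the phenotype correlation matrix is estimated
    from cross-trait LD score regression intercepts, phenotypes are
    hierarchically clustered at every possible number of clusters, a
    chi-square quadratic-form statistic is computed for each partition, and
    the resulting p-values are aggregated with the Cauchy combination.
    Also provides the SSU, Hom, Wald, PCFisher and aMAT comparison tests,
    an exact weighted-chi-square (Imhof) tail oracle, a simulation toolkit
    for type-I error and power studies under block AR(1) correlation
    structures, readers and writers for summary-statistic and LD score
    files, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
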