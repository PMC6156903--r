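Package: wepistasis
Title: W-Test for SNP-CpG Epistasis in Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects statistical interactions between genetic variants (SNPs)
    and DNA methylation (CpG beta values) on a binary phenotype using the
    W-test, a distribution-comparison statistic that sums squared standardized
    log odds ratios over joint genotype-methylation categories. The null
    distribution is calibrated to a scaled chi-squared by bootstrap moment
    matching, making the test adaptive to the structure of the working data.
    Includes readers for tabular genotype/methylation/phenotype formats,
    additive genotype coding and two-mean methylation binarization, cis-window
    SNP-CpG pair scanning with Bonferroni correction and Q-Q diagnostics,
    logistic-regression interaction benchmarks, and a synthetic-cohort
    simulator for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
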