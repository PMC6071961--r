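Package: tabexact
Title: Exact and Asymptotic Significance Indices for Contingency Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Significance indices for hypothesis tests in contingency tables
    under small sample sizes.  The central index is an exact likelihood-ratio
    p-value obtained by eliminating the nuisance parameter from the null
    likelihood through integration, enumerating the complete sample space of
    tables, and summing the resulting null probabilities over the critical
    region defined by the likelihood-ratio statistic.  Alongside it the package
    computes the asymptotic likelihood-ratio and Pearson chi-square p-values,
    Fisher's conditional exact test, Barnard's unconditional exact test, and
    the Full Bayesian Significance Test e-value (Monte Carlo and asymptotic),
    for three classical hypotheses: homogeneity of independent multinomial
    rows, independence of two classifiers, and Hardy-Weinberg equilibrium of
    genotype counts.  Drivers are included to evaluate every index over all
    tables of a sample space and to map exact and Monte Carlo power surfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
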