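Package: cnidilemma
Title: CNI Model and Process Dissociation Analysis of Moral Dilemma Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing two-group sacrificial moral dilemma batteries
    (6 stories crossed with proscriptive/prescriptive norms and
    benefits-greater/benefits-smaller consequences). Implements the traditional
    utilitarian score, process-dissociation estimation of utilitarian (U) and
    deontological (D) inclinations, and maximum-likelihood fitting of the CNI
    multinomial processing tree (sensitivity to Consequences, sensitivity to
    moral Norms, generalized Inaction) on aggregate condition counts, with
    G-squared goodness of fit, likelihood-ratio constraint tests, and Wald
    confidence intervals. Includes reconstruction of aggregate counts from
    printed condition means, the surrounding classical statistics (mixed 2x2
    ANOVA with simple effects, rank correlations, chi-squared, summary-statistic
    t-tests), and a synthetic respondent generator for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
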