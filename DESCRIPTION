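Package: otocost
Title: Cost-Minimization Modelling of Genotype-Guided Chemotherapy for
    Cisplatin Ototoxicity
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian decision-analytic cost-minimization analysis of
    GSTP1 c.313A>G genotype-guided chemotherapy in head-and-neck cancer.
    Estimates the decision-tree arm probabilities by beta-binomial
    Metropolis-Hastings sampling (with a conjugate closed-form oracle),
    compares first-year expected per-patient costs between conventional
    cisplatin treatment and a genotype-guided strategy under
    batch-dependent genotyping economics with equipment amortization,
    locates the break-even cohort size, and projects the cohort through a
    ten-year three-state Markov model (alive without hearing loss, alive
    with hearing loss, dead) with annual discounting of audiological-care
    savings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
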