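Package: uratesim
Title: Semi-Mechanistic Uric Acid Exposure-Response Modelling for URAT1
    Inhibitor and Xanthine Oxidase Inhibitor Combinations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and nonlinear mixed-effects estimation tools for a
    semi-mechanistic turnover model of uric acid disposition under treatment
    with a URAT1 inhibitor (verinurad), xanthine oxidase inhibitors
    (febuxostat, allopurinol via oxypurinol), or their combination. Includes
    analytic population-pharmacokinetic exposure drivers, covariate models on
    fractional excretion and potency, correlated lognormal between-subject
    variability, clinical trial simulation with variability and parameter
    uncertainty, Laplace-approximation population estimation with empirical
    Bayes estimates and predictive checks, and a virtual-study generator
    producing NONMEM-style longitudinal datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
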