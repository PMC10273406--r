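Package: virtrial
Title: In Silico Clinical Trials with Virtual Populations, Whole-Body
    Pharmacokinetics and Signed-Network Drug Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for in silico clinical trials of CNS stimulants in
    attention-deficit/hyperactivity disorder (ADHD). Generates randomized
    virtual patient cohorts matched to reference trial demographics, simulates
    per-patient drug exposure with a 14-compartment physiologically based
    pharmacokinetic (PBPK) model, trains ensembles of signed protein-network
    weight assignments ("mathematical solutions") against drug-efficacy
    restrictions, and propagates patient-specific target stimuli to bounded
    protein activities. Includes the downstream analysis battery: the tSignal
    efficacy proxy, reverted-protein classification, hypergeometric enrichment,
    one-at-a-time stimulus sensitivity sweeps, random target-set extension
    robustness, and demographic, comorbidity and co-treatment effect
    statistics with Benjamini-Hochberg correction. All external inputs
    (protein network, disease definition, expression data, drug pools,
    reference demographics) can be generated synthetically with controlled
    statistical structure, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
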