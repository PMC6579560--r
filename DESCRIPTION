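Package: phagedyn
Title: Phage Perturbation Dynamics in Defined Gut Bacterial Communities
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of lytic-phage perturbations in defined
    (gnotobiotic) gut bacterial consortia. Provides a generalized
    Lotka-Volterra community simulator with mass-action phage predation and
    a susceptible/resistant subpopulation split; an observation model
    emitting 16S copy-number-weighted sequencing counts, universal-16S and
    phage-specific qPCR measurements, and producer-coupled metabolite
    tables; absolute bacterial abundance estimation from relative 16S
    fractions and qPCR totals with copy-number correction and non-detect
    imputation; perturbation fold-change analysis; dropout-based
    interaction-network inference with knockdown response prediction;
    longitudinal Bray-Curtis stability statistics; and FDR-controlled
    metabolite differential analysis. Observed datasets are handled as
    SummarizedExperiment objects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    vegan,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software, TimeCourse, Metabolomics
RoxygenNote: 7.3.3
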