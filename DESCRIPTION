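Package: cagdyn
Title: Somatic CAG Expansion Indices and Transcriptional Rescue Analysis
    in Huntington Disease Mouse Models
Version: 0.1.0
Authors@R: person("cagdyn", "developers", role = c("aut", "cre"),
    email = "cagdyn@example.org")
Description: Quantifies somatic CAG repeat instability from fragment-analysis
    peak traces (modal-allele calling and expansion indices), tests
    differential gene expression across Htt x Hdac2 genotype groups with an
    in-package negative-binomial likelihood-ratio test, classifies
    dysregulated genes into rescued and exacerbated categories by directional
    overlap and endpoint t-tests, runs gene-set permutation tests for reduced
    relative impact of the disease allele, relates nuclear-pathology
    intensities to expansion indices, and computes contraction-assay fold
    changes.  Ships synthetic-data generators with known ground truth so the
    entire pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
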