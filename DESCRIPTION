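Package: phenodem
Title: Dementia Phenotyping from Electronic Health Records with Stable
    Topics and Max-Margin Risk Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying patients with probable undiagnosed
    dementia from electronic health record (EHR) data. Clinical-note content
    is summarised by stable topics extracted from three independently seeded
    latent Dirichlet allocation runs, converted to pseudo word counts and a
    bounded topic-presence score per patient. Structured codes (diagnoses,
    procedures, medications, note types) become binary indicators, with
    ICD-9 and ICD-10 diagnosis codes bridged across the coding transition by
    decomposing the general equivalence mapping into minimal disjoint
    bipartite groups. A linear support vector machine, with its cost
    parameter chosen by cross-validated AUC, converts the features into an
    unbounded dementia risk score. Scores are validated under a stratified
    chart-review sampling design using inverse-probability-weighted
    estimates of prevalence, sensitivity, specificity, predictive values and
    a weighted ROC, with stratified bootstrap confidence intervals and
    Cohen's kappa for inter-rater agreement. A synthetic EHR cohort
    generator with planted topic and code signal supports end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
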