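Package: survsel
Title: Survival-Informed Gene Selection for Metastasis Prognosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers prognostic transcript panels from paired expression
    and disease-free-survival data. A bi-objective combinatorial genetic
    algorithm with orthogonal-array crossover searches fixed-size transcript
    subsets, scoring each by a weighted blend of leave-one-out RBF-SVM
    classification accuracy and the normalized area between the Kaplan-Meier
    disease-free-survival curves of the predicted groups. Post-search tools
    aggregate appearance frequencies across independent runs, refine panels
    by sequential backward selection, evaluate them with random-subspace SVM
    ensembles, and predict survival times by support-vector regression. A
    synthetic-cohort generator reproduces the assumed data structure for
    testing end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    survival,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
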