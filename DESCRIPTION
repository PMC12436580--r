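Package: epdscat
Title: Computer-Adaptive Short Forms of the Edinburgh Postnatal Depression Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graded response item response theory models for the 10-item
    Edinburgh Postnatal Depression Scale (EPDS) under one-, two- and
    three-factor simple structures, fitted by marginal maximum likelihood
    EM over a fixed quadrature grid. Includes expected a posteriori (EAP)
    trait scoring with an empirical-reliability shrinkage correction,
    real-data computerized adaptive testing (CAT) simulation with
    maximum-information start, posterior-weighted-information and
    trace-rule item selection and a trait-change stopping rule,
    expected-total-score risk classification with a suicidal-ideation
    override, screening accuracy metrics (NPV, PPV), Cronbach's alpha, and
    a false-negative-rate parity fairness audit across demographic groups.
    A synthetic-cohort generator emulates the statistical structure of a
    postpartum screening population so the whole pipeline can be exercised
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
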