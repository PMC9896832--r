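Package: oksmap
Title: Response Mapping from the Oxford Knee Score to EQ-5D-5L Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Indirect (response) mapping from the 12-item Oxford Knee Score
    to the five EQ-5D-5L domains for knee-osteoarthritis cohorts. Implements
    four ordinal model families (cumulative link models with five link
    functions, penalized cumulative regression with AIC/BIC-selected ridge or
    lasso penalties, cost-sensitive ordinal classification trees built on the
    generalized Gini impurity, and ordinal forests with score-set
    optimization), four predictor-set constructions (all items, recursive
    feature elimination, model-based importance, principal components), a
    repeated cross-validated model tournament over the full hyperparameter
    grid, profile-to-utility conversion through pluggable country value sets,
    and error evaluation with bootstrap percentile confidence intervals. A
    calibrated single-factor synthetic cohort generator emulating the joint
    OKS/EQ-5D-5L structure of knee-osteoarthritis samples makes the whole
    pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ranger,
    stats,
    tools,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
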