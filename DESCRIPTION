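Package: emoprofiler
Title: Composite Emotionality Scoring and Individual-Level Cluster
    Profiling for Factorial Behavioral Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for multivariate behavioral phenotyping of rodent
    cohorts from 2x3 factorial designs (prenatal exposure by rearing
    environment). Builds a composite emotionality score by z-transforming
    behavioral measures, orienting scales, and selecting the item subset
    with maximal Cronbach's alpha internal consistency; runs the group
    statistics used in such studies (type III factorial ANOVA with
    Bonferroni-corrected pairwise comparisons and automatic Welch
    correction, variance F tests, Fisher's and Barnard's exact tests for
    rare binary outcomes, Spearman rank correlations); and characterizes
    inter-individual differences by Ward hierarchical clustering of
    squared Euclidean distances with core and predicted cluster profiles.
    Includes a synthetic cohort generator reproducing the statistical
    structure the analysis assumes, so the full pipeline is testable
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    ape,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
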