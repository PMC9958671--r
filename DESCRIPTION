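Package: uromet
Title: Exercise-Response Analysis of Paired Urine and Plasma Metabolomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for untargeted urine metabolomics
    exercise-response studies with a paired plasma panel. Covers
    osmolality normalization, minimum-value imputation, median centering,
    a generalized-log variance-stabilizing transform and the modified 80
    percent detection filter; per-metabolite linear mixed models with
    cohort-by-timepoint interaction contrasts and Satterthwaite degrees
    of freedom; Kolmogorov-Smirnov enrichment over non-overlapping
    metabolite sets; pathway topology impact scoring via relative
    betweenness centrality with a permutation global test; cross-biofluid
    Pearson correlation screening with robust outlier removal; and Ward
    hierarchical clustering of subjects. Includes a synthetic-data
    generator with known ground truth for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest
Config/testthat/edition: 3
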