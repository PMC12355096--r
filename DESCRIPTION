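Package: chcv
Title: Clonal Hematopoiesis and Cardiovascular Outcomes in Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying clonal hematopoiesis (CH) and
    cardiovascular outcomes in cancer cohorts. Implements a post-calling
    filter cascade that turns candidate somatic variants with read-level
    evidence into per-participant CHIP (clonal hematopoiesis of
    indeterminate potential) status; classification of mosaic chromosomal
    alteration (mCA) calls into LOY/LOX/autosomal/expanded categories;
    cohort eligibility rules and per-endpoint time-to-event construction;
    logistic prevalence models; Cox proportional-hazards models with a
    four-category CH exposure; and additive/multiplicative interaction
    metrics (RERI, attributable proportion, multiplicative interaction
    ratio, classical synergy index) with delta-method or bootstrap
    confidence intervals. A fully synthetic cohort generator with known
    ground truth makes every stage testable without access to any
    biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    survival,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
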