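Package: metaboclass
Title: Chemometric Classification of Serum Metabolomics Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate classification toolkit for GC-MS serum metabolomics
    cohorts. Implements internal-standard normalization via a non-centered
    principal component model, NIPALS principal component analysis with
    cross-validated Q2 and distance-to-model (DModX) statistics, SIMCA soft
    classification with F-based critical distances and Coomans coordinates,
    two-class OPLS-DA with p(corr) discriminatory profiles, CV-ANOVA and
    ROC/sensitivity/specificity evaluation from cross-validated predictions,
    weighted dot-product spectral match scoring with retention-index
    verification, and a seeded synthetic cohort generator emulating a
    multi-group autoimmune-disease study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
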