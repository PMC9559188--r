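Package: drbilat
Title: Interval-Dependent Dimensional-Reduction Prognostic Modelling for
    Metachronous Bilateral Breast Cancer
Version: 0.1.0
Authors@R:
    person("R.", "Mills", email = "rmills@example.org",
           role = c("aut", "cre"))
Description: Competing-risk prognostic modelling for metachronous bilateral
    breast cancer (MBBC). Implements nonparametric cumulative-incidence
    (Aalen-Johansen) estimation, Fine-Gray subdistribution-hazard regression,
    estimation of interval-time-dependent weights for paired primary and
    contralateral tumor features from cumulative-incidence-area contrasts,
    arctan weight-curve fitting, dimensional-reduction (DR) staging of
    bilateral T stage, N stage, grade and ER status, a competing-risk
    nomogram for breast-cancer-specific cumulative mortality, cohort
    splitting, a competing-risk concordance index and bootstrap calibration,
    mutant-allele tumor heterogeneity (MATH) statistics, and a synthetic
    MBBC cohort generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
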