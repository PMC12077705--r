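Package: gliopfs
Title: Automated Progression-Free Survival Endpoints from Glioblastoma EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives progression-free survival (PFS) endpoints for glioblastoma
    patients from three electronic-health-record modalities: dexamethasone
    taper courses in prescription tables, rule-based natural-language analysis
    of brain-MRI radiology reports with ConText-style modifier attribution, and
    longitudinal contrast-enhancing tumor volumes under a relative-change
    threshold. Endpoints are compared against a clinical-standard (RANO chart
    review) date with Table-style descriptive statistics, Kruskal-Wallis and
    exact Wilcoxon signed-rank tests with Bonferroni correction, and
    ordinary-least-squares trendlines. A seeded synthetic EHR cohort generator
    with known ground truth makes every stage testable without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
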