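Package: insituCEA
Title: Markov Cohort Cost-Effectiveness Analysis of Surgical Strategies for
    In Situ Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A six-state Markov cohort model comparing mastectomy, lumpectomy
    without irradiation and lumpectomy with irradiation for carcinoma in situ
    of the breast (ICD-10 D05) in Sweden over a 30-year horizon. Implements
    the full decision-analytic pipeline: rate and cumulative-incidence
    conversion to annual transition probabilities, an age-specific background
    mortality overlay, discounted cost and QALY accumulation under healthcare
    and societal perspectives, incremental cost-effectiveness analysis with
    strong and extended dominance elimination and Swedish willingness-to-pay
    categories, and probabilistic sensitivity analysis with cost-effectiveness
    plane and acceptability-curve outputs. Ships synthetic stand-ins for the
    two confidential or external inputs: a Gompertz-Makeham life table and a
    patient-level surgical cost registry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
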