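Package: octpower
Title: Sample Size and Power for OCT Retinal-Layer Endpoints in Optic
    Neuritis Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Design tools for two-arm parallel neuroprotection trials in
    AQP4-IgG seropositive optic neuritis that use optical coherence
    tomography (OCT) summary measures of the macular ganglion cell plus
    inner plexiform layer (mGCIPL) as the endpoint. Summarizes per-eye
    longitudinal thickness/volume records, translates an assumed
    protective effect size into a mean difference, estimates per-arm and
    total sample sizes by the two-sample normal-approximation formula
    (from follow-up values or from change scores), evaluates the exact
    two-term analytic power, and validates designs by Monte Carlo
    simulation against a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
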