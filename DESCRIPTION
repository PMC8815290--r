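Package: lifespacer
Title: GPS Life-Space Excursions, Prospective Falls, and Visual Field
    Staging for Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies away-from-home excursions from minute-epoch GPS
    traces (home anchoring from night-time fixes, 50-m home margin,
    valid-day quality control, home/away segmentation), classifies
    prospective fall status from monthly falls calendars (faller,
    recurrent, injurious, recurrent injurious), builds the integrated
    visual field from paired-eye 24-2 sensitivities with
    Hodapp-Parrish-Anderson-derived severity staging, and fits negative
    binomial incidence-rate-ratio models and generalized estimating
    equations linking fall status to excursion parameters over repeated
    visits. Includes a synthetic cohort generator with known latent truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    geosphere,
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
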