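Package: scanbias
Title: Expected-Value Bias Analysis for Fetal Growth Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and quantifies expected-value (observer) bias in fetal
    growth ultrasound scans from operator eye-tracking streams and
    measurement-event logs. Provides fixation detection on the on-screen
    measurement box, reconstruction of caliper-measurement episodes, bias-event
    detection, classification of caliper adjustments toward or away from the
    expected gestational age, cohort-level incidence tables and paired
    before/after deviation statistics, estimated-fetal-weight (EFW) bounds with
    discordance and SGA/AGA/LGA reclassification, pluggable fetal growth
    standards (Hadlock dating, EFW and EFW-for-GA references shipped as
    configuration), and a synthetic scan-session simulator with known ground
    truth for end-to-end validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    broom,
    withr
Config/testthat/edition: 3
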