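Package: liprod
Title: Low-Input Dairy Production Scoring and Breed Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing dairy breeds under low-input and organic
    management. Implements a quintile-based composite low-input-production
    (LI-P) score combining milk yield and solids, udder health (somatic cell
    count and treatment records) and nine milk fatty-acid variables; breed
    code canonicalisation and cohort inclusion filtering; per-date
    standardized principal components ordination; and linear mixed-effects
    breed comparison with farm and season as crossed random factors. A
    calibrated synthetic herd generator (17-farm roster, eight breed-group
    trait distributions, moment-matched lognormal somatic cell counts and
    negative-binomial treatment counts) makes every stage testable without
    access to the original herd records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    lme4,
    lmerTest,
    ggplot2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
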