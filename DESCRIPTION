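Package: healthproj
Title: Multi-State Markov Projection of Disability and Health Expectancy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time multi-state Markov cohort model for projecting
    cardiovascular disease, cognitive impairment, dementia, disability and
    mortality in a national population aged 35-100 by sex and calendar year.
    Provides a ten-state state space, validated transition-probability
    schedules, calendar-trend scenario construction, an annual-cycle
    projection engine with population conservation guarantees, disability
    counts and directly age-standardised prevalence, period life tables and
    Sullivan-method decomposition of life expectancy into disabled and
    disability-free components, and Monte Carlo probabilistic sensitivity
    analysis with Dirichlet-sampled transition rows. A synthetic-data
    generator emulates the longitudinal-study and official-statistics inputs
    the model consumes, with controllable ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
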