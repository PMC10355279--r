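Package: nightcross
Title: Sea-Crossing Flight Analysis for Nocturnal Bird Migrants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A biologging analysis pipeline for open-water crossings by
    nocturnally migrating birds. Reconstructs great-circle tracks from
    nightly GPS fixes, intersects them with coastline polygons to obtain
    open-water distances and crossing times, classifies arrivals as diurnal
    or nocturnal from solar geometry, converts multisensor-logger pressure
    records to barometric altitude under the International Standard
    Atmosphere, computes accelerometer flight-activity indices and segments
    flight episodes, evaluates wind-support hypotheses by heading-compensated
    ground speeds over gridded winds, and fits the associated mixed-effects
    and regression models. Includes a synthetic-data generator that emulates
    the sampling design of nightjar tracking studies so that every stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    glmmTMB,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
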