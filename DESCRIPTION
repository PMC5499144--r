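Package: qfascreen
Title: Quantitative Fitness Analysis for Genome-Wide Genetic Interaction Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative fitness analysis (QFA) of arrayed
    colony-growth screens in budding yeast. Fits logistic growth curves to
    timed colony-intensity series, summarizes each culture as Maximum
    Doubling Rate times Maximum Doubling Potential (doublings squared per
    day), scores genetic interactions between a query mutation and a
    genome-wide deletion library against a multiplicative independence
    model, and ranks gene deletions by the similarity of their fitness
    profiles across screens. Includes a ground-truthed synthetic screen
    generator (paired control and query backgrounds, replicate cultures,
    planted suppressors and enhancers, dead cultures, chronic or
    acute-temperature treatments) so the whole pipeline can be validated
    without raw plate images, plus tab-delimited readers and writers and a
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    ggplot2,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
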