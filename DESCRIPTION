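Package: cocount
Title: Crossover Interference and Synaptonemal Complex Morphometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of crossover (recombination-focus) patterning along
    meiotic chromosome axes from cytological focus-position tables.
    Implements maximum-likelihood fitting of the gamma shape parameter to
    inter-focus spacings, the coefficient-of-coincidence (CoC) construction
    with an interference distance at CoC = 0.5, focus-count distributions
    (E-distribution, obligatory crossover), per-nucleus morphometry
    (segment numbers, SC lengths, crossover density, count-versus-length
    regression), and a stationary gamma renewal-process simulator of
    crossover placement, including obligate-crossover and fragmented-SC
    modes, so every stage of the analysis is testable on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    xml2,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
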