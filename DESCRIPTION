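Package: semilunar
Title: Circasemilunar Emergence-Rhythm Analysis and Clock-Architecture
    Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Period estimation and hypothesis testing for circasemilunar
    (about 15-day) and circadian emergence rhythms of intertidal insects
    such as the marine midge Clunio marinus.  Reads daily and hourly
    emergence-count series with missing values, estimates free-running
    periods by Lomb-Scargle periodograms and a JTK-style nonparametric
    scan integrated meta2d-style (mean period, Fisher-combined p,
    Benjamini-Hochberg correction), and discriminates day-counter,
    independent-oscillator and circadian/circatidal-beat clock
    architectures from period-versus-T-cycle data by AICc model selection
    with Akaike weights.  A population emergence simulator generates
    ground-truth series under each architecture, including circadian
    entrainment limits, frequency demultiplication under short T-cycles
    and desynchronization under constant light.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
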