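Package: tercab
Title: Terrestrial Ecosystem Carbon Balance Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the carbon balance of terrestrial
    ecosystems from annual land-cover, productivity and climate rasters.
    Implements land-use carbon-storage bookkeeping from per-class
    four-pool carbon densities, a net-ecosystem-productivity model (NPP
    minus soil heterotrophic respiration), per-pixel linear-trend
    analysis with F-test significance classes, partial-correlation
    screening of climate drivers, residual-trend attribution of climate
    versus human contributions, the geographical-detector q statistic
    with interaction detection, and land-use transfer matrices.  A
    synthetic-scene generator with known ground truth (climate trends,
    Markov land-use transitions, injected disturbance patches) makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
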