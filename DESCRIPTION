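Package: dickinsonia
Title: Growth Simulation and Morphometrics of Modular Ovoid Body Plans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the development of Dickinsonia costata-like modular
    ovoid organisms under isometric outline growth, posterior terminal
    addition and regulated module inflation, degrades the resulting
    specimens the way fossil preservation does (grain-size resolution
    censoring, soft-body distortion, completeness filtering), measures
    them with the standard morphometric protocol (total length and
    width, module lengths at midline and outer margin, module width,
    anterior-most unit), and computes population-level growth statistics:
    length-width isometry regressions with F- and t-tests, linear and
    power-law module-number scaling, the adjacent-module outer-margin
    increase statistic, anterior-most-unit comparisons, and normalized
    module-number profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
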