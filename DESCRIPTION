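Package: redoxmap
Title: Isomorphous Difference Maps, Extrapolated Structure Factors and
    Flavin Bending Analysis for Two-State Crystals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing redox-state-dependent structural changes
    in isomorphous crystal pairs: q-weighted Fo-Fo difference electron
    density maps, extrapolated structure factors with occupancy estimation
    by an inflection scan of integrated residual negative density,
    difference-map real-space correlation (dFoCC) refinement of flavin
    isoalloxazine butterfly bending, and geometry/B-factor/ADP analytics.
    Includes a synthetic two-state crystal generator with known ground
    truth so every stage of the pipeline can be validated end to end.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
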