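Package: treelinetopo
Title: Topoclimatic Indices and Treeline Elevation Deviation Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing local-scale variability in alpine treeline
    elevation from hourly mountain meteorology and digital elevation models.
    Computes stress indices for photoinhibition, summer and winter
    desiccation, and radiative frost, plus total daytime insolation, from
    hourly temperature, wind, humidity and radiation series; derives Horn
    slope and Zevenbergen-Thorne curvature from elevation rasters; builds a
    site-relative elevation-deviation response; and runs the explanatory
    chain of standardized principal components analysis, random-forest
    variable importance with partial dependence, and a conditional
    inference tree whose splits require Monte-Carlo permutation
    significance. Includes seeded synthetic generators for terrain, hourly
    meteorology, treeline points and regional covariates so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
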