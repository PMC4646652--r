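Package: birdscape
Title: Linked Landowner Decision and Grassland Bird Population Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A coupled social-biological simulator for grassland bird
    conservation planning. An agent-based land-cover choice model converts
    policy-dependent landowner preference weights over five objectives
    (grassland birds, carbon storage, water quality, financial profit,
    biodiversity) into per-pixel probabilities of grassland, agriculture or
    forest cover via a simple multi-attribute rating of land-cover utilities.
    The resulting raster landscapes drive a spatially explicit full-annual-cycle
    population model (breeding, fall migration, wintering, spring migration)
    with neighbourhood-dependent reproduction, stopover occupancy and forage
    survival, and seasonal carrying capacities. Scenario machinery produces
    policy-by-landowner consequence tables of mean annual population growth
    rates, a grassland-cover response curve, and a derivative-free calibration
    routine that fits demographic parameters to a reference consequence table.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    lhs
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
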