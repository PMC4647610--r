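Package: reefscore
Title: Computational Aesthetic Scoring of Coral Reef Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts photographs of benthic coral-reef scenes into a
    continuous aesthetic value. Implements a registry of 109 aesthetic
    image features spanning colour and brightness of the whole image,
    the size, colour and spatial distribution of discernable objects,
    and surface texture; calibrates the feature vectors against
    site-level anthropogenic-impact scores with a single-hidden-layer
    feed-forward neural network; aggregates predictions over multiple
    images per site; ranks features by random-forest importance; and
    ships a seeded synthetic reefscape generator so the whole pipeline
    can be exercised without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools,
    png,
    jpeg,
    tiff,
    igraph,
    nnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
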