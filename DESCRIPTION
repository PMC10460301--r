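Package: siterep
Title: Representativeness and Constituency Analysis for Environmental Site Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how well a network of experimental sites represents the
    environmental conditions of a gridded landscape. Environmental driver layers
    are reduced to a principal-component feature space; representativeness is
    one minus the normalized multivariate Euclidean distance between each site
    centroid and every grid cell; constituency assigns each cell to its
    best-representing site. Includes a seeded synthetic-landscape generator
    (Gaussian random fields, categorical land-use masks, clustered site
    networks), per-site area and distribution summaries, generalist/specialist
    site diagnostics, cross-network complementarity maps, and an end-to-end
    reproducible pipeline with text-format raster and GeoJSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
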