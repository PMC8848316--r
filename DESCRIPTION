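Package: gradphen
Title: Image-Based Plant Phenotyping Under LED Light-Quality Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying plant phenotypic responses to a continuous
    red:blue light-quality gradient from side- and top-view RGB images. The
    package generates complete in-silico gradient experiments (layout, light
    map, procedural plant scenes with ground truth), segments plant silhouettes
    from calibrated images, computes dimension, shape-factor and colour-index
    descriptors (solidity, circularity, Feret diameters, GLI, TGI, predicted
    chlorophyll, and more), estimates per-descriptor gradient effect sizes by
    regression on the log red:blue ratio over a time course, and discriminates
    species by principal component analysis over descriptor subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils,
    tools,
    png,
    EBImage,
    yaml,
    cluster,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
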