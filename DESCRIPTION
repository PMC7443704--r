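Package: consat
Title: Circuit Extraction and Saturation Sampling for Sparse EM Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing sparsely reconstructed electron-microscopy
    connectomes of the Drosophila thermo- and hygrosensory system: randomized
    downstream-postsynapse sampling with a saturation stopping rule,
    threshold-based circuit extraction from polyadic synapse tables,
    NBLAST-style morphology similarity scoring with Ward clustering for neuron
    typing, a bouton-share bootstrap null model for Kenyon-cell claw input
    composition, cable-length versus receptor-neuron-input regression, and a
    seeded synthetic-connectome generator that emulates the relevant data
    structures (SWC skeletons, polyadic connectors, neuropil volumes,
    glomeruli, boutons, claws) with ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    yaml,
    ape,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
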