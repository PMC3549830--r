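Package: solvmsm
Title: Markov State Models with Solvent Degrees of Freedom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Markov state models (MSMs) from molecular-dynamics
    trajectories while retaining solvent degrees of freedom. Provides a
    permutation-invariant Gaussian solvent signature and the induced
    Euclidean metric between configurations, Kabsch-aligned solute RMSD,
    fast k-center/k-medoid geometric splitting under either metric, a
    product (combination) clustering that crosses solute and solvent
    clusters, transition-count and column-stochastic transition-matrix
    estimation, metastability-maximizing lumping of microstates into
    macrostates by simulated annealing, and a continuous water-number
    observable for concave solutes such as nanopores. Includes synthetic
    trajectory generators (a single-file channel-filling model and a
    two-basin solute-plus-solvent model) with known ground truth, readers
    and writers for multi-frame XYZ and multi-model PDB, broom-style
    tidiers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
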