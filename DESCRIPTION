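Package: iriscreen
Title: Machine-Learning Discovery of Small-Molecule Ice Recrystallisation Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative structure-activity modelling and virtual screening of
    small-molecule ice recrystallisation inhibitors (IRIs). Implements six
    molecular representations -- standard physicochemical descriptors, molecular
    clique fingerprints, histogrammed weighted atom-centred symmetry functions,
    atom-averaged SOAP power spectra, and two trajectory-derived hydration
    descriptors (water-solute distance histograms and hydration indices) --
    together with ensemble feed-forward neural-network classification and
    regression of percent mean grain size (MGS) under leave-one-out cross
    validation with SMOTE balancing, exhaustive ensemble-combination search,
    and a virtual-screening filter cascade (Tanimoto similarity to activity
    seeds, training-set overlap, co-salt and logP filters, ensemble-uncertainty
    filtering). Includes seeded generators for synthetic solvated trajectories
    with planted hydration shells and synthetic structure-activity tables so
    the full pipeline is testable without molecular-dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with rdkit, on the PATH as 'python'
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
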