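Package: ecsmediv
Title: Extended Continuous Similarity Indices and Diversity Selection for
    Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes extended (n-ary) continuous similarity indices over sets
    of molecular conformations and selects maximally diverse, representative
    frames from molecular dynamics trajectories with the linearly scaling
    ECS-MeDiv picker (medoid seeding by complementary similarity followed by
    greedy extended-similarity minimisation).  Includes readers for multi-model
    PDB, XYZ trajectories and plain coordinate matrices, average pairwise RMSD
    evaluation of selections, a seeded multi-basin/drift trajectory simulator
    for validation, and a command-line front end.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
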