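Package: g3ps
Title: Greedy 3-Point Search Pharmacophore Alignment and Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body alignment of 3D pharmacophore models that maximizes
    the number of geometrically matched feature pairs under per-feature
    positional tolerances. Implements the Greedy 3-Point Search strategy:
    features are encoded by their labelled neighbourhood-distance profiles,
    a dissimilarity matrix ranks three-pair seed correspondences, and each
    seed is grown by Kabsch superposition with a monotone forbidden-pair
    matrix. Includes exclusion-volume checking with dodging translations,
    direction-vector post-filters, a distance-histogram baseline aligner
    with Hungarian assignment and iterative pair removal, a virtual
    screening driver with omitted-feature budgets, readers and writers for
    a native JSON schema and a plain-text phar dialect, and generators for
    synthetic pharmacophores with known ground-truth correspondences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
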