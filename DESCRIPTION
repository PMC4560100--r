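Package: swapsmith
Title: Repeat-Swap Homology Modeling of Inverted-Topology Transporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for repeat-swap homology modeling of secondary active
    transporters built from inverted-topology structural repeats. From a
    single known conformation the package constructs the swapped template,
    the duplicated target-template alignment, and the Gaussian distance
    restraints needed to model the complementary conformation, and
    quantifies the predicted elevator-type conformational change (rotation
    axis and angle, membrane-normal translation, per-residue displacement,
    per-domain RMSD and TM-score). Includes a synthetic generator of toy
    two-repeat transporters with known ground truth, a naive
    coordinate-transfer model builder for dependency-free testing, and
    emission of complete Modeller-ready input bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
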