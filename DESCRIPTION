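Package: coextinct
Title: Host Extinction and the Reshaping of Parasite Host Specificity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how host extinction reshapes the apparent
    host specificity of parasites. Computes evolutionary distinctiveness
    (equal-splits and fair-proportion) on rooted host phylogenies and the
    ED gains that follow from pruning extinct taxa; represents bipartite
    host-parasite association networks with IUCN threat attributes;
    simulates ordered extinction scenarios (threat-ordered or randomised)
    with coextinction rules, recording per-parasite host richness and mean
    pairwise phylogenetic distance (MPD) trajectories and classifying
    per-parasite outcomes; and provides a multi-host optimal-virulence
    model describing how a shared virulence strategy shifts when hosts are
    lost. A synthetic-data module generates birth-death host trees,
    phylogenetically structured association networks and trait-biased
    threat statuses so the whole pipeline is testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
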