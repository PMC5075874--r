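Package: nemasurv
Title: Automated Image Analysis for C. elegans Killing Assays in Microfluidic Chambers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fully automated nematode killing assays imaged in
    microfluidic chambers. Bright-field and fluorescence time-lapse frames are
    segmented into worm-associated pixels; connected components holding several
    touching worms are split into individuals using narrow body regions,
    boundary turn-angle analysis at worm-worm junctions, and an average-length
    ruler for end-to-end chains. Each worm is scored dead or alive from its
    opacity against an adaptive neighborhood threshold, and per-worm
    fluorescence, opacity and motility are quantified. Survival curves are
    built without censoring for chamber assays and with the Kaplan-Meier
    product-limit estimator for plate-style records. A synthetic scene
    generator produces ground-truthed chamber images (pillar lattice, curved
    worm bodies, touching-worm clusters, post-mortem opacity decay) so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    EBImage,
    tiff,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Visualization, Survival, Software
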