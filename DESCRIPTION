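Package: plaquemorph
Title: 3D Morphometry of Immunogold-Labelled Gap-Junction Plaques in
    Volume Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs and measures connexin-43 gap-junction plaques at
    the cardiomyocyte intercalated disc from serial block-face scanning
    electron microscopy (SBF-SEM) stacks in which the protein is labelled
    with silver-enhanced nanogold beads. Provides a synthetic stack
    generator with complete ground truth, a scale-space dark-blob bead
    detector, reconstruction of the two apposed bead strings per plaque
    and slice, per-plane intercellular-space metrics (length, area, area
    per length, maximal width), detection of hemiplaques (runs of label on
    one membrane lacking opposing partners), and two-group statistics with
    a Shapiro-Wilk / Lilliefors-corrected Kolmogorov-Smirnov normality
    gate routing to Student's t or Mann-Whitney tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    jsonlite,
    yaml,
    nortest,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
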