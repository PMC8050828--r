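Package: guvpart
Title: Partitioning of Membrane-Anchored Species Between Lipid Phases
    of Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how fluorescently labelled, membrane-anchored
    species (such as amphiphilic DNA nanostructures) distribute between
    coexisting liquid-ordered (Lo) and liquid-disordered (Ld) phases of
    phase-separated giant unilamellar vesicles, starting from two-channel
    equatorial confocal images.  Provides a synthetic image generator with
    known ground truth, vesicle ring detection with sub-pixel circle
    fitting, angular intensity profiling, two-arc (Janus) phase
    segmentation, background and spectral cross-talk correction,
    per-vesicle fractional intensities and partitioning free energies, an
    additive multi-anchor free-energy model, population-level statistics,
    and a fuel/antifuel-driven discrete state machine with exponential
    relaxation for ligand-triggered redistribution experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    ggplot2,
    grDevices,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
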