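Package: perizone
Title: Quantification of Synaptic Protein Organization in STED and
    Enhanced-Confocal Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image-quantification pipelines for sub-synaptic protein
    localization. Extracts, aligns and summarizes perpendicular line
    profiles at side-view synapses in STED images of cultured neurons;
    detects protein clusters around the active zone at en-face synapses;
    quantifies protein levels within Otsu-derived presynaptic masks at
    confocal resolution; and performs bouton-level and periactive-zone-level
    quantification of Drosophila neuromuscular junction volumes, including
    seeded region growing segmentation of periactive-zone units, mesh/core
    polarization, Bruchpilot object density and Brp/Pak unit classification.
    A synthetic-microscopy generator with exhaustive ground truth makes
    every stage verifiable by parameter recovery, and a statistics layer
    implements assumption-gated test selection with Tukey-Kramer or Holm
    corrections and Pearson colocalization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    Rcpp,
    car,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
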