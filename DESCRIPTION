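Package: espray
Title: Electrospray Cell-Encapsulation Device Fields and Assay Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the needle-plate electrospray device used for cell
    encapsulation and differentiation studies, and quantifies the assays
    around it. Solves Poisson's equation over the device cross-section by
    finite differences (axisymmetric or planar), extracts tip-region
    electric-field metrics and profiles, evaluates the electrohydrodynamic
    force scales that set the spraying mode and droplet-size bounds, and
    summarises the field and shear exposure of cells in transit. Downstream
    stages quantify high-speed droplet frames and brightfield spheroid
    images, and implement LDH viability, delta-delta-Ct relative expression,
    differential-expression filtering with gene-ontology tallies, and group
    comparisons. Synthetic-data generators with planted ground truth stand in
    for all wet-lab inputs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
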