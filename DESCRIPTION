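Package: opcrkin
Title: Dental Complexity, Occlusal Kinematics and Multimodel Selection for
    Carnivorous Mammal Tooth Rows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes orientation patch count (OPC) and its rotation-averaged
    form (OPCR) from gridded three-dimensional tooth-row surfaces, reads and
    writes the surface formats used in dental topographic analysis (PLY
    meshes, XYZ point clouds, Surfer ASCII grids), derives relative measures
    of mandibular motion from specimen measurements, and compares candidate
    generalized-least-squares models of tooth-row complexity by maximum
    likelihood, small-sample Akaike information criterion (AICc), Akaike
    weights, confidence sets and model averaging. Ships a 34-specimen
    carnivoran and dasyuromorph measurement table and synthetic surface and
    specimen-table generators for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
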