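Package: kidneysim
Title: Hybrid Force-Based and Position-Based-Dynamics Soft-Body Simulator
    for Laparoscopic Partial-Nephrectomy Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless soft-tissue simulator reproducing the physics of a
    laparoscopic partial-nephrectomy (LPN) trainer: triangle-mesh soft bodies
    driven by a mass-spring-pressure force model with semi-implicit Euler
    integration, combined with a position-based-dynamics (PBD) constraint
    solver handling stretch, dihedral bending and static-collider contact.
    Connections are breakable at a configurable threshold, so a marked cut
    path tears and the labelled tumour region of a procedurally generated
    kidney phantom can be resected. Includes mesh I/O (OBJ, PLY, STL),
    deterministic synthetic fixtures, an interaction layer (ray picking,
    cut-path marking, resection), and a batch simulation driver with metrics
    logging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
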