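Package: fabrifem
Title: Fabric-Based Finite-Element Modelling of Trabecular Bone
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing constitutive models of trabecular bone in
    linear finite-element analyses of proximal-femur-like structures. Estimates
    mean-intercept-length (MIL) fabric tensors from binarized micro-CT-style
    volumes, maps bone volume fraction (BV/TV) and fabric onto tetrahedral
    meshes, builds per-element orthotropic stiffness with the Zysset-Curnier
    power law, solves the static elastic problem under muscle and joint-reaction
    loads, and post-processes principal fields, strain energy density and Frost
    mechanostat zones along anatomical paths. Includes generators for synthetic
    trabecular volumes and surrogate femur meshes so the whole pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
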